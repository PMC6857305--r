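test_that("catalog simulation is seed-deterministic and conserves burdens", {
  ref <- reference_signatures("cosmic_v2_synthetic")[, c("Sig3", "Sig5")]
  expo <- cbind(c(300, 700, 500), c(700, 300, 500))
  s1 <- simulate_catalog(ref, expo, seed = 42)
  s2 <- simulate_catalog(ref, expo, seed = 42)
  expect_identical(s1$spectra, s2$spectra)
  expect_equal(unname(rowSums(s1$spectra)), c(1000, 1000, 1000))
  expect_identical(s1$truth, expo)
  expect_error(simulate_catalog(ref, cbind(0, 0)), "zero total")
  expect_error(simulate_catalog(ref, cbind(-1, 2)), "negative")
})

test_that("a one-signature draw converges on its generator", {
  ref <- reference_signatures("cosmic_v2_synthetic")
  s <- simulate_catalog(ref[, c("Sig3", "Sig5")], cbind(1e5, 0), seed = 2)
  expect_gte(cosine_similarity(s$spectra[1, ], ref[, "Sig3"]), 0.99)
})

test_that("separability declines gracefully to zero error", {
  # orthogonal one-hot "signatures" separate at modest burden
  a <- c(rep(1 / 48, 48), rep(0, 48))
  b <- c(rep(0, 48), rep(1 / 48, 48))
  sep <- separability_experiment(a, b, n_samples = 8,
                                 muts_per_sample = 500, replicates = 2,
                                 seed = 4, n_restarts = 8)
  expect_lt(sep$mae, 0.5)
  # near-noiseless limit
  ref <- reference_signatures("cosmic_v2_synthetic")
  sep2 <- separability_experiment(ref[, "Sig3"], ref[, "Sig5"],
                                  n_samples = 8, muts_per_sample = 1e6,
                                  replicates = 1, seed = 4,
                                  n_restarts = 8)
  expect_lte(sep2$mae, 0.5)
  expect_error(separability_experiment(a, a), "identical")
})

test_that("planted indel contexts verify against the string oracles", {
  for (mix in list(c("repeat" = 1, microhomology = 0, none = 0),
                   c("repeat" = 0, microhomology = 1, none = 0),
                   c("repeat" = 0, microhomology = 0, none = 1))) {
    sim <- simulate_genome_with_indels(16000, class_mix = mix,
                                       n_events = 20, seed = 55)
    g <- as.character(sim$genome[[1]])
    for (i in seq_len(nrow(sim$catalog))) {
      rec <- sim$catalog[i, ]
      L <- nchar(rec$ref) - 1
      deleted <- substr(rec$ref, 2, nchar(rec$ref))
      left <- substr(g, max(1, rec$pos - 6 * L), rec$pos)
      right <- substr(g, rec$pos + L + 1, min(nchar(g), rec$pos + 7 * L))
      cls <- names(mix)[mix == 1]
      if (cls == "repeat") {
        expect_gte(oracle_tandem(deleted, left, right), 2)
      } else if (cls == "microhomology") {
        expect_equal(oracle_mh(deleted, left, right),
                     sim$truth$truth_mh_length[i])
        expect_equal(oracle_tandem(deleted, left, right), 1)
      } else {
        expect_equal(oracle_mh(deleted, left, right), 0)
        expect_equal(oracle_tandem(deleted, left, right), 1)
      }
    }
  }
})

test_that("the deletion classifier recovers planted classes exactly", {
  sim <- simulate_genome_with_indels(25000,
                                     class_mix = c("repeat" = 0.4,
                                                   microhomology = 0.4,
                                                   none = 0.2),
                                     n_events = 30, seed = 77)
  calls <- do.call(rbind, lapply(seq_len(nrow(sim$catalog)), function(i)
    classify_deletion(sim$catalog[i, ], sim$genome)))
  expect_equal(calls$context_class, sim$truth$truth_class)
  mh_idx <- sim$truth$truth_class == "microhomology"
  expect_equal(calls$mh_length[mh_idx], sim$truth$truth_mh_length[mh_idx])
})

test_that("empty simulations are valid", {
  sim <- simulate_genome_with_indels(5000, n_events = 0, seed = 1)
  expect_null(sim$catalog)
  expect_equal(Biostrings::width(sim$genome), 5000)
  sv <- simulate_sv_catalog(reference_signatures("rs_breast_synthetic"),
                            c(1, 0, 0, 0, 0, 0), n_events = 0)
  expect_equal(sum(sv$truth_channels), 0)
})

test_that("simulated SV catalogs round-trip through the classifier", {
  rs <- reference_signatures("rs_breast_synthetic")
  contrib <- c(RS1 = 0, RS2 = 0, RS3 = 0, RS4 = 0, RS5 = 1, RS6 = 0)
  sim <- simulate_sv_catalog(rs, contrib, n_events = 500, seed = 12)
  expect_identical(
    simulate_sv_catalog(rs, contrib, n_events = 500, seed = 12)$svs,
    sim$svs)
  bp <- rbind(data.frame(chrom = sim$svs$chrom1, pos = sim$svs$pos1),
              data.frame(chrom = sim$svs$chrom2, pos = sim$svs$pos2))
  flags <- detect_clusters(bp)
  clustered <- flags[seq_len(nrow(sim$svs))] |
    flags[nrow(sim$svs) + seq_len(nrow(sim$svs))]
  cat32 <- classify_rearrangements(sim$svs, clustered)
  expect_equal(sum(cat32), 500)
  # classified channels match the drawn truth closely (clustered calls on
  # a pure non-clustered draw can only arise from chance dense runs)
  fit <- fit_rearrangement_signatures(cat32, rs)
  expect_gte(fit$contributions["RS5"], 0.95)
})

test_that("clustered channels produce detectable dense runs", {
  rs <- reference_signatures("rs_breast_synthetic")
  contrib <- c(0, 0.5, 0, 0, 0, 0.5)  # RS2 scattered + RS6 clustered
  sim <- simulate_sv_catalog(rs, contrib, n_events = 300, seed = 14)
  truth_cl <- grepl("^clustered", sim$svs$truth_channel)
  bp <- rbind(data.frame(chrom = sim$svs$chrom1, pos = sim$svs$pos1),
              data.frame(chrom = sim$svs$chrom2, pos = sim$svs$pos2))
  flags <- detect_clusters(bp)
  clustered <- flags[seq_len(nrow(sim$svs))] |
    flags[nrow(sim$svs) + seq_len(nrow(sim$svs))]
  # most planted clustered events are flagged, few scattered ones are
  expect_gt(mean(clustered[truth_cl]), 0.8)
  expect_lt(mean(clustered[!truth_cl]), 0.2)
})
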