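sv_row <- function(sample, chrom1, pos1, chrom2, pos2, type, softclips) {
  d <- data.frame(sample = sample, chrom1 = chrom1, pos1 = pos1,
                  chrom2 = chrom2, pos2 = pos2, type = type,
                  softclips = softclips, stringsAsFactors = FALSE)
  d$size <- ifelse(d$chrom1 == d$chrom2, abs(d$pos2 - d$pos1),
                   NA_integer_)
  d
}

full_coverage <- function(svs, samples, depth = 20) {
  bp <- unique(rbind(data.frame(chrom = svs$chrom1, pos = svs$pos1),
                     data.frame(chrom = svs$chrom2, pos = svs$pos2)))
  do.call(rbind, lapply(samples, function(s)
    data.frame(sample = s, chrom = bp$chrom, pos = bp$pos, depth = depth)))
}

test_that("SV post-filters enforce support, uniqueness and coverage", {
  svs <- rbind(
    sv_row("s1", "chr1", 10000, "chr1", 60000, "deletion", 12),
    sv_row("s1", "chr2", 5000, "chr2", 900000, "deletion", 4),    # support
    sv_row("s1", "chr3", 1000, "chr3", 21000, "inversion", 9),    # shared
    sv_row("s2", "chr3", 1005, "chr3", 400000, "deletion", 9))    # shared
  cov <- full_coverage(svs, c("s1", "s2"))
  kept <- filter_svs(svs, cov)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$pos1, 10000)
  # support of exactly 5 passes
  svs5 <- sv_row("s1", "chr1", 10000, "chr1", 60000, "deletion", 5)
  expect_equal(nrow(filter_svs(svs5, full_coverage(svs5, "s1"))), 1)
  # zero coverage in any sample removes the record
  cov0 <- cov
  cov0$depth[cov0$sample == "s2" & cov0$pos == 10000] <- 0
  expect_equal(nrow(filter_svs(svs, cov0)), 0)
  # missing coverage entries are an error naming the sample
  expect_error(filter_svs(svs, cov[cov$sample != "s2", ]),
               "missing coverage entry for sample s2")
})

test_that("SV filtering is order-independent", {
  set.seed(61)
  svs <- do.call(rbind, lapply(1:12, function(i)
    sv_row(sample(c("s1", "s2"), 1), "chr1", i * 50000,
           "chr1", i * 50000 + 25000, "deletion", sample(3:8, 1))))
  cov <- full_coverage(svs, c("s1", "s2"))
  kept1 <- filter_svs(svs, cov)
  perm <- sample(nrow(svs))
  kept2 <- filter_svs(svs[perm, ], cov)
  key <- function(d) sort(paste(d$sample, d$pos1, d$pos2))
  expect_equal(key(kept1), key(kept2))
})

test_that("rearrangement channels partition every classified SV", {
  svs <- rbind(
    sv_row("s", "chr1", 1e6, "chr1", 1e6 + 50000, "deletion", 9),
    sv_row("s", "chr1", 2e6, "chr1", 2e6 + 10000, "deletion", 9),
    sv_row("s", "chr2", 1e6, "chr2", 1e6 + 5e6, "tandem-duplication", 9),
    sv_row("s", "chr2", 1e7, "chr2", 1e7 + 2e7, "inversion", 9),
    sv_row("s", "chr3", 1e6, "chr4", 2e6, "CTX", 9),
    sv_row("s", "chr5", 1e6, "chr5", 1e6 + 3000, "insertion", 9))
  cat32 <- classify_rearrangements(svs, clustered = FALSE)
  expect_equal(sum(cat32), 6)
  # bins are half-open with exclusive upper edge, so the 50 kb deletion
  # and the one of exactly 10 kb both sit in [10, 100) kb
  expect_equal(unname(cat32["non-clustered:del:10-100kb"]), 2)
  expect_equal(unname(cat32["non-clustered:dup:1-10Mb"]), 1)
  expect_equal(unname(cat32["non-clustered:inv:>10Mb"]), 1)
  expect_equal(unname(cat32["non-clustered:trans"]), 1)
  expect_equal(unname(cat32["non-clustered:dup:1-10kb"]), 1)
  # clustered flags route to clustered channels
  cat_cl <- classify_rearrangements(svs[5, ], clustered = TRUE)
  expect_equal(unname(cat_cl["clustered:trans"]), 1)
  # ITX is excluded and counted
  itx <- sv_row("s", "chr1", 1e6, "chr1", 3e6, "ITX", 9)
  cat_itx <- classify_rearrangements(itx)
  expect_equal(sum(cat_itx), 0)
  expect_equal(attr(cat_itx, "n_itx"), 1L)
  # sub-kb events warn and land in the smallest bin
  tiny <- sv_row("s", "chr1", 1e6, "chr1", 1e6 + 500, "deletion", 9)
  expect_warning(cat_t <- classify_rearrangements(tiny), "1 kb")
  expect_equal(unname(cat_t["non-clustered:del:1-10kb"]), 1)
})

test_that("too few breakpoints or uniform spacing yield no clusters", {
  expect_false(any(detect_clusters(seq(1e6, 9e6, length.out = 9))))
  expect_false(any(detect_clusters(seq(1e6, 99e6, length.out = 40))))
})

test_that("a dense breakpoint run inside a sparse chromosome is flagged", {
  set.seed(71)
  sparse <- sort(runif(30, 1, 1e8))
  dense <- 5e7 + sort(runif(20, 0, 1e4))
  pos <- c(sparse, dense)
  flags <- detect_clusters(pos)
  expect_true(all(flags[31:50]))
  expect_lt(mean(flags[1:30]), 0.2)
})

test_that("segmentation matches the exhaustive changepoint oracle", {
  set.seed(81)
  for (i in 1:6) {
    n <- sample(25:45, 1)
    y <- c(rnorm(n %/% 2, 0, 0.3), rnorm(n - n %/% 2, sample(c(0, 3), 1),
                                         0.3))
    kmin <- 10; gamma <- sample(c(2, 25), 1)
    seg <- hrsig:::pcf_segment(y, kmin, gamma)
    # cost of the returned segmentation
    cost <- sum(vapply(split(y, seg), function(s)
      sum((s - mean(s))^2), numeric(1))) + gamma * (max(seg) - 1)
    oracle <- oracle_segment(y, kmin, gamma)
    expect_equal(cost, oracle$cost, tolerance = 1e-9)
  }
})

test_that("rearrangement signature fits recover planted mixtures", {
  rs <- reference_signatures("rs_breast_synthetic")
  # pure RS5 catalog
  fit <- fit_rearrangement_signatures(500 * rs[, "RS5"], rs)
  expect_equal(unname(fit$contributions["RS5"]), 1, tolerance = 1e-6)
  # noiseless 70/30 mixture of RS5 and RS3, cross-checked by grid oracle
  mix <- 700 * rs[, "RS5"] + 300 * rs[, "RS3"]
  fit2 <- fit_rearrangement_signatures(mix, rs[, c("RS5", "RS3")])
  expect_equal(unname(fit2$contributions), c(0.7, 0.3), tolerance = 1e-6)
  gx <- oracle_nnls2(rs[, c("RS5", "RS3")], mix)
  expect_equal(gx[1] / sum(gx), 0.7, tolerance = 0.01)
  expect_true(kkt_ok(rs[, c("RS5", "RS3")], mix, fit2$exposures))
  expect_error(fit_rearrangement_signatures(numeric(32), rs), "empty")
})
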