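#!/usr/bin/env Rscript
# Builds the synthetic reference signature sets shipped under inst/extdata/.
#
# These are SYNTHETIC stand-ins for published reference sets that cannot be
# redistributed here: a 30-signature x 96-channel SNV set in the style of
# COSMIC v2, and a 6-signature x 32-channel rearrangement set in the style
# of the breast-cancer rearrangement signatures. Each synthetic signature
# encodes the documented qualitative shape of its namesake (class weights
# and context texture), not its exact published values. In particular the
# two flat "featureless" signatures 3 and 5 are constructed so that their
# cosine similarity reproduces the published similarity of the real pair
# (~0.83), which is what governs how hard they are to separate.
#
# Deterministic: fixed seed; re-running reproduces the shipped files.

suppressMessages(devtools::load_all("."))
set.seed(20191114)

bases <- c("A", "C", "G", "T")
ch <- sbs_channels()

# per-signature class weights over C>A, C>G, C>T, T>A, T>C, T>G and a
# context-texture concentration (high = flat contexts, low = spiky)
spec <- list(
  Sig1  = list(w = c(.10, .06, .60, .06, .12, .06), a = 1.5, mask = "cpg"),
  Sig2  = list(w = c(.05, .10, .70, .05, .07, .03), a = 1.0, mask = "tpc"),
  Sig3  = list(w = c(.17, .12, .30, .12, .18, .11), a = 8.0, mask = "none"),
  Sig4  = list(w = c(.55, .10, .15, .08, .08, .04), a = 2.0, mask = "none"),
  Sig5  = list(w = c(.09, .06, .35, .09, .33, .08), a = 8.0, mask = "none"),
  Sig6  = list(w = c(.10, .05, .60, .05, .15, .05), a = 1.2, mask = "cpg"),
  Sig7  = list(w = c(.05, .05, .75, .05, .05, .05), a = 1.0, mask = "pyr5"),
  Sig8  = list(w = c(.45, .15, .15, .10, .10, .05), a = 4.0, mask = "none"),
  Sig9  = list(w = c(.08, .05, .10, .12, .55, .10), a = 2.0, mask = "none"),
  Sig10 = list(w = c(.45, .05, .40, .03, .04, .03), a = 0.6, mask = "tpc"),
  Sig11 = list(w = c(.08, .04, .70, .05, .08, .05), a = 3.0, mask = "none"),
  Sig12 = list(w = c(.06, .04, .12, .10, .58, .10), a = 2.5, mask = "none"),
  Sig13 = list(w = c(.05, .65, .15, .05, .06, .04), a = 1.0, mask = "tpc"),
  Sig14 = list(w = c(.25, .05, .45, .05, .15, .05), a = 1.5, mask = "none"),
  Sig15 = list(w = c(.10, .05, .65, .05, .10, .05), a = 1.0, mask = "gpc"),
  Sig16 = list(w = c(.05, .03, .08, .10, .64, .10), a = 1.5, mask = "none"),
  Sig17 = list(w = c(.04, .03, .06, .07, .20, .60), a = 0.8, mask = "none"),
  Sig18 = list(w = c(.60, .10, .10, .08, .08, .04), a = 1.5, mask = "none"),
  Sig19 = list(w = c(.10, .08, .40, .10, .22, .10), a = 3.0, mask = "none"),
  Sig20 = list(w = c(.20, .05, .55, .05, .10, .05), a = 1.2, mask = "gpc"),
  Sig21 = list(w = c(.05, .03, .08, .08, .66, .10), a = 1.2, mask = "none"),
  Sig22 = list(w = c(.08, .04, .08, .65, .10, .05), a = 1.0, mask = "none"),
  Sig23 = list(w = c(.08, .05, .62, .08, .10, .07), a = 1.5, mask = "none"),
  Sig24 = list(w = c(.55, .08, .20, .06, .07, .04), a = 1.5, mask = "none"),
  Sig25 = list(w = c(.08, .05, .10, .55, .15, .07), a = 1.5, mask = "none"),
  Sig26 = list(w = c(.06, .04, .25, .08, .50, .07), a = 1.2, mask = "none"),
  Sig27 = list(w = c(.06, .04, .08, .60, .15, .07), a = 1.0, mask = "none"),
  Sig28 = list(w = c(.06, .04, .08, .08, .14, .60), a = 1.0, mask = "none"),
  Sig29 = list(w = c(.55, .12, .15, .07, .07, .04), a = 1.5, mask = "none"),
  Sig30 = list(w = c(.12, .07, .45, .10, .16, .10), a = 5.0, mask = "none")
)

context_mask <- function(kind) {
  m <- rep(1, 16)  # order: 5' A,C,G,T major; 3' A,C,G,T minor
  five <- rep(bases, each = 4); three <- rep(bases, 4)
  if (kind == "cpg") m[three == "G"] <- 8          # NpCpG emphasis
  if (kind == "tpc") m[five == "T"] <- 8           # TpC emphasis
  if (kind == "gpc") m[five == "G"] <- 6
  if (kind == "pyr5") m[five %in% c("C", "T")] <- 6
  m
}

make_sig <- function(s) {
  out <- numeric(96)
  for (ci in 1:6) {
    tex <- rgamma(16, shape = s$a, rate = 1)
    tex <- tex * context_mask(s$mask)
    tex <- tex / sum(tex)
    out[(ci - 1) * 16 + 1:16] <- s$w[ci] * tex
  }
  out / sum(out)
}

cos96 <- matrix(NA_real_, 96, length(spec),
                dimnames = list(ch$label, names(spec)))
for (nm in names(spec)) cos96[, nm] <- make_sig(spec[[nm]])

cs <- cosine_similarity(cos96[, "Sig3"], cos96[, "Sig5"])
message(sprintf("synthetic Sig3 vs Sig5 cosine similarity: %.3f", cs))

out <- data.frame(channel = ch$label, round(cos96, 6),
                  check.names = FALSE)
write.table(out, "inst/extdata/cosmic_v2_synthetic_signatures.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# ---- synthetic rearrangement signatures (32 channels, 6 signatures) ----
rch <- rearrangement_channels()
w32 <- function(weights) {
  v <- setNames(rep(0.1, 32), rch)  # smoothing floor
  for (nm in names(weights)) v[nm] <- v[nm] + weights[[nm]]
  v / sum(v)
}
rs <- cbind(
  RS1 = w32(c("non-clustered:dup:100kb-1Mb" = 8,
              "non-clustered:dup:1-10Mb" = 8,
              "non-clustered:dup:>10Mb" = 2)),
  RS2 = w32(c("non-clustered:del:100kb-1Mb" = 4,
              "non-clustered:del:1-10Mb" = 4,
              "non-clustered:inv:100kb-1Mb" = 3,
              "non-clustered:inv:1-10Mb" = 3,
              "non-clustered:trans" = 4)),
  RS3 = w32(c("non-clustered:dup:1-10kb" = 10,
              "non-clustered:dup:10-100kb" = 8)),
  RS4 = w32(c("clustered:trans" = 12,
              "clustered:del:1-10kb" = 2,
              "clustered:inv:1-10kb" = 2)),
  RS5 = w32(c("non-clustered:del:1-10kb" = 10,
              "non-clustered:del:10-100kb" = 7,
              "non-clustered:del:100kb-1Mb" = 2)),
  RS6 = w32(c("clustered:inv:1-10kb" = 5,
              "clustered:inv:10-100kb" = 5,
              "clustered:del:10-100kb" = 3,
              "clustered:dup:10-100kb" = 2))
)
out <- data.frame(channel = rch, round(rs, 6), check.names = FALSE)
write.table(out, "inst/extdata/rs32_synthetic_signatures.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote inst/extdata reference sets")
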