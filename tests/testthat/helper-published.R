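# Published study fixtures: the per-sample unique-marker counts of the
# 34-wine botrytized-wine panel and its printed consistency-score profile.
published_rums_counts <- c(
  AU1 = 65, AU2 = 620, AU3 = 105, AU4 = 14, AU5 = 13, AU6 = 7, AU7 = 19,
  AU8 = 34, FR1 = 10, FR2 = 19, FR3 = 1, FR4 = 142, FR5 = 170, FR6 = 101,
  FR7 = 22, FR8 = 10, HU1 = 29, HU2 = 125, HU3 = 133, HU4 = 61, HU5 = 42,
  HU6 = 78, SK1 = 34, SK2 = 73, SK3 = 30, SK4 = 64, SK5 = 9, SK6 = 11,
  SK7 = 62, SK8 = 219, SK9 = 291, SK10 = 61, SK11 = 82, SK12 = 36)

published_pq <- c(34, 795, 871, 924, 971, 980, 981, 976, 986, 993, 991,
                  970, 928, 755)

# stand-in marker sets carrying the published cardinalities (vectors are
# placeholders; only the counts matter for pooling)
counts_as_rums <- function(counts) {
  out <- lapply(names(counts), function(id) {
    n <- counts[[id]]
    fake_rums(matrix(rep(c(1, 0), each = n), ncol = 2), id)
  })
  names(out) <- names(counts)
  out
}
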