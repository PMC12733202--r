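# Published per-position predominance (percent) of the PELP1 LM/PM motifs.
# Only residues contributing more than 10% at a position are listed; the
# remaining probability mass is unattributed and is spread uniformly over
# the unlisted canonical residues when building an emission distribution.
# LM8 position 2 lists a second percentage without a residue symbol in the
# published table; only the attributable R(78) is encoded.
MOTIF_PREDOMINANCE <- list(
  LM1 = list(c(L = 60, A = 13), c(R = 56, M = 18), c(L = 57, R = 24),
             c(L = 72, R = 11), c(L = 82, T = 10)),
  PM1 = list(c(P = 63, S = 26), c(V = 80), c(H = 60, L = 16),
             c(P = 66, L = 18)),
  PM2 = list(c(P = 43, E = 37), c(H = 46, Y = 31), c(L = 84), c(P = 84)),
  LM2 = list(c(L = 79), c(L = 43, M = 40), c(C = 44, A = 34),
             c(L = 46, N = 28), c(L = 48, Y = 38)),
  LM3 = list(c(L = 95), c(L = 95), c(S = 85), c(L = 54, M = 21, V = 16),
             c(L = 92)),
  LM4 = list(c(L = 98), c(R = 43, K = 27, Q = 18), c(D = 89), c(L = 88),
             c(L = 95)),
  LM5 = list(c(L = 52, I = 40), c(P = 65, L = 33), c(G = 91),
             c(L = 62, I = 36), c(L = 94), c(T = 93), c(S = 92), c(L = 97),
             c(L = 96)),
  LM6 = list(c(L = 65, I = 19), c(H = 77), c(S = 47, C = 40), c(L = 92),
             c(L = 94)),
  LM7 = list(c(L = 63, A = 34), c(H = 65, N = 30), c(S = 48, G = 26, T = 12),
             c(L = 71), c(L = 94)),
  LM8 = list(c(L = 80, V = 14), c(R = 78), c(L = 82), c(L = 90),
             c(L = 60, V = 29)),
  LM9 = list(c(L = 68, F = 27), c(T = 25, S = 23, A = 12), c(H = 90),
             c(L = 94), c(L = 84)),
  PM3 = list(c(P = 80), c(S = 60, G = 28), c(A = 59, P = 27),
             c(P = 61, R = 27)),
  LM10 = list(c(L = 98), c(Y = 95), c(R = 72, C = 11), c(L = 91), c(L = 97)),
  LM11 = list(c(L = 95), c(A = 92), c(L = 93), c(L = 55, V = 39), c(L = 95))
)

#' Per-position emission distribution matching the published motif consensus
#'
#' Builds a per-position categorical emission table for one of the fourteen
#' PELP1 motifs whose probabilities equal the published percentage
#' predominance values; the unattributed remainder at each position is
#' spread uniformly over the unlisted canonical residues. Sampling motif
#' instances from this table and recomputing [position_frequencies()]
#' recovers the published percentages (up to multinomial noise), which is
#' the package's end-to-end consensus-recovery check.
#'
#' @param motif_id One of `LM1`-`LM11`, `PM1`-`PM3`.
#' @return Numeric matrix, positions x 20 residues; every row sums to 1.
#' @examples
#' emission_for_table4("LM3")["pos3", "S"]  # 0.85
#' @export
emission_for_table4 <- function(motif_id) {
  if (!motif_id %in% names(MOTIF_PREDOMINANCE)) {
    stop("validation error: unknown motif '", motif_id, "'")
  }
  rows <- MOTIF_PREDOMINANCE[[motif_id]]
  mat <- t(vapply(rows, function(listed) {
    p <- setNames(numeric(20L), AA20)
    p[names(listed)] <- listed / 100
    rest <- setdiff(AA20, names(listed))
    p[rest] <- (1 - sum(listed) / 100) / length(rest)
    p
  }, numeric(20L)))
  rownames(mat) <- paste0("pos", seq_len(nrow(mat)))
  mat
}
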