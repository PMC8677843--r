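#' Stratified train/validation/test split
#'
#' Partitions units into the named fractions within every stratum
#' (by default the seven Gi-bins), so that each partition preserves the
#' spatial-cluster composition of the full table. Per-stratum counts are
#' fixed by largest-remainder rounding (each partition's count differs
#' from `fraction * N_stratum` by less than one unit); assignment within
#' a stratum is a seeded shuffle, so the same seed reproduces the split
#' exactly. Strata with fewer units than partitions are sent wholly to
#' the first partition with a warning.
#'
#' @param strata Vector of stratum labels, one per unit (e.g. `gi_bin`).
#' @param fractions Named positive fractions summing to 1; names are the
#'   partition labels. Default 70/15/15 train/valid/test.
#' @param seed Optional integer seed.
#' @return A factor of partition labels (levels in `names(fractions)`)
#'   with the stratum vector attached as attribute `strata`.
#' @examples
#' split <- stratified_split(rep(0, 100), seed = 1)
#' table(split)
#' @export
stratified_split <- function(strata,
                             fractions = c(train = 0.70, valid = 0.15,
                                           test = 0.15),
                             seed = NULL) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    stop("fractions must be named (partition labels)")
  if (any(fractions <= 0)) stop("fractions must be positive")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n <- length(strata)
  parts <- names(fractions)
  P <- length(parts)

  assign_one <- function() {
    out <- character(n)
    for (s in unique(strata)) {
      idx <- which(strata == s)
      Ns <- length(idx)
      if (Ns < P) {
        warning("stratum '", s, "' has fewer units (", Ns,
                ") than partitions; all assigned to '", parts[1], "'")
        out[idx] <- parts[1]
        next
      }
      exact <- fractions * Ns
      base <- floor(exact)
      rem <- Ns - sum(base)
      if (rem > 0) {
        extra <- order(-(exact - base), seq_len(P))[seq_len(rem)]
        base[extra] <- base[extra] + 1
      }
      idx <- idx[sample.int(Ns)]
      out[idx] <- rep(parts, times = base)
    }
    out
  }
  out <- if (is.null(seed)) assign_one() else withr::with_seed(seed, assign_one())
  structure(factor(out, levels = parts), strata = strata)
}
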