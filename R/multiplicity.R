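#' Permute case/control labels
#'
#' Shuffles the `status` column while keeping every covariate attached to its
#' sample. The stratified scheme (default) permutes labels within strata
#' defined by ethnicity crossed with institution, preserving the
#' frequency-matched design; the simple scheme shuffles across the whole
#' table. A stratum of size one keeps its label.
#'
#' @param samples Sample table.
#' @param scheme `"stratified"` or `"simple"`.
#' @param seed Optional integer; when supplied the permutation stream is
#'   reproducible (`set.seed` is called).
#' @return The sample table with permuted `status`.
#' @export
permute_phenotype <- function(samples, scheme = c("stratified", "simple"),
                              seed = NULL) {
  scheme <- match.arg(scheme)
  samples <- validate_samples(samples)
  if (!is.null(seed)) set.seed(seed)
  if (scheme == "simple") {
    samples$status <- sample(samples$status)
    return(samples)
  }
  key <- interaction(samples$ethnicity, samples$institution, drop = TRUE)
  for (lev in levels(key)) {
    idx <- which(key == lev)
    if (length(idx) > 1L)
      samples$status[idx] <- sample(samples$status[idx])
  }
  samples
}

#' Min-P permutation family-wise error control for one level of tests
#'
#' For each of `B` permutations the supplied callback recomputes every test
#' at the level on permuted data and the minimum p-value is stored. The
#' adjusted p-value of a test with observed p-value `p0` is
#' `(1 + #\{b : minP_b <= p0\}) / (B + 1)`, so adjusted p-values are bounded
#' below by `1/(B+1)` and are monotone in the observed p-values; they are
#' additionally clipped from below at the observed p-value (the population
#' min-P adjustment can never be smaller, so any crossing is Monte-Carlo
#' noise).
#'
#' @param observed Named numeric vector of observed p-values at the level
#'   (tests reported as not performed must be removed by the caller).
#' @param B Number of permutations (the study default is 1000).
#' @param callback Function of one argument, the permutation index `b`,
#'   returning the vector of recomputed p-values for that permutation. Any
#'   failure or missing value aborts the procedure.
#' @param seed Integer seed for the permutation stream; `set.seed(seed)` is
#'   called once before the loop so the callback can rely on the session RNG.
#' @return An object of class `permutation_summary`: list with `B`, `seed`,
#'   `observed`, `min_p` (length-B empirical distribution), `adjusted`.
#' @export
minp_fwer <- function(observed, B, callback, seed) {
  if (!length(observed) || anyNA(observed))
    stop("observed p-values must be non-empty and non-missing")
  if (any(observed < 0 | observed > 1)) stop("p-values must lie in [0, 1]")
  B <- as.integer(B)
  if (B < 1L) stop("B must be at least 1")
  set.seed(seed)
  min_p <- numeric(B)
  for (b in seq_len(B)) {
    p <- tryCatch(callback(b), error = function(e)
      stop("test recomputation failed on permutation ", b, ": ",
           conditionMessage(e)))
    if (!length(p) || anyNA(p))
      stop("callback returned missing p-values on permutation ", b)
    min_p[b] <- min(p)
  }
  adj <- vapply(observed, function(p0) (1 + sum(min_p <= p0)) / (B + 1),
                numeric(1))
  adj <- pmax(adj, observed)
  structure(list(B = B, seed = seed, observed = observed, min_p = min_p,
                 adjusted = pmin(adj, 1)),
            class = "permutation_summary")
}

#' @export
print.permutation_summary <- function(x, ...) {
  cat("permutation_summary:", length(x$observed), "tests, B =", x$B, "\n")
  print(data.frame(test = names(x$observed), p_observed = x$observed,
                   p_adjusted = x$adjusted, row.names = NULL))
  invisible(x)
}
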