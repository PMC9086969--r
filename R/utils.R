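#' @keywords internal
"_PACKAGE"

# Per-stage substreams of one global seed, so each pipeline stage is
# independently reproducible. Values stay below 2^31 - 1.
.STAGES <- c(
  model = 1L, families = 2L, phenotypes = 3L, split = 4L, gwas = 5L,
  tune = 6L, boot = 7L, models = 8L, stratify = 9L, screen = 10L
)

#' Derive a per-stage seed from a global seed
#'
#' Each stochastic stage of the pipeline draws its seed deterministically
#' from the single run-level seed, so stages can be re-run in isolation.
#'
#' @param seed integer global seed.
#' @param stage stage name, one of `"model"`, `"families"`, `"phenotypes"`,
#'   `"split"`, `"gwas"`, `"tune"`, `"boot"`, `"models"`, `"stratify"`,
#'   `"screen"`.
#' @return An integer seed below 2^31.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stage <- match.arg(stage, names(.STAGES))
  k <- .STAGES[[stage]]
  as.integer((abs(as.numeric(seed)) * 48271 + k * 99991) %% 2147483629)
}

# Wilson score interval for a binomial proportion.
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Truncated-normal draw via inverse CDF (no rejection, fully vectorised).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm((lo - mean) / sd)
  phi <- stats::pnorm((hi - mean) / sd)
  mean + sd * stats::qnorm(stats::runif(n, plo, phi))
}

is_binary01 <- function(x) {
  is.numeric(x) && all(x %in% c(0, 1))
}

# Coerce case/control labels to 0/1.
as_status01 <- function(status) {
  if (is.logical(status)) return(as.integer(status))
  if (is.factor(status)) status <- as.character(status)
  if (is.character(status)) {
    ok <- status %in% c("case", "control")
    if (!all(ok)) stop("status labels must be 'case'/'control'", call. = FALSE)
    return(as.integer(status == "case"))
  }
  if (!is_binary01(status)) {
    stop("status must be binary (0/1, logical, or 'case'/'control')",
         call. = FALSE)
  }
  as.integer(status)
}
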