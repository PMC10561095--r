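#' Generate synthetic indicator data for region pairs
#'
#' Emulates the kind of raw data from which inter-region correlation
#' strengths are derived: for `h` regions, one `h x h` matrix per indicator
#' holding a nonnegative raw value for every region pair. The default five
#' indicators are the ones that drive inter-region epidemic transmission:
#' geographic distance (inverse direction — farther apart means less risk),
#' personnel flow, economic traffic, transport convenience and logistics
#' intensity (all proportional — more exchange means more risk). Entries
#' are drawn independently and uniformly from `range`; real indicator data
#' are of course spatially structured and mutually correlated, so this
#' generator exercises the pipeline's contracts rather than mimicking any
#' particular geography (see the vignette).
#'
#' @param h number of regions, at least 2.
#' @param seed integer seed; the same seed always yields identical data.
#' @param indicators character vector of indicator names.
#' @param directions per-indicator risk direction, `"proportional"` or
#'   `"inverse"`.
#' @param range length-2 numeric, the sampling range (default `c(0, 1)`).
#' @param symmetric draw symmetric matrices (`b[m, s] == b[s, m]`,
#'   default `TRUE`), as for undirected quantities like distance.
#' @return an [indicator_data()] object.
#' @export
#' @examples
#' ind <- generate_synthetic_indicators(h = 6, seed = 7)
#' ind
generate_synthetic_indicators <- function(h, seed,
    indicators = c("distance", "personnel_flow", "economic_traffic",
                   "transport_convenience", "logistics_intensity"),
    directions = c("inverse", rep("proportional", length(indicators) - 1)),
    range = c(0, 1), symmetric = TRUE) {
  h <- as.integer(h)
  if (is.na(h) || h < 2)
    stop("`h` must be an integer >= 2", call. = FALSE)
  if (missing(seed) || is.null(seed))
    stop("a `seed` is required for reproducible synthetic data", call. = FALSE)
  stopifnot(length(range) == 2, range[1] < range[2], range[1] >= 0)
  mats <- with_seed(seed, {
    lapply(seq_along(indicators), function(i) {
      B <- matrix(stats::runif(h * h, range[1], range[2]), h, h)
      if (symmetric) B[lower.tri(B)] <- t(B)[lower.tri(B)]
      B
    })
  })
  names(mats) <- indicators
  indicator_data(mats, directions)
}
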