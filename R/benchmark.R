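#' Bundled 50-region benchmark networks
#'
#' The package ships two benchmark datasets used throughout its tests and
#' documentation: the same 50-region network topology (49 tree edges plus
#' three same-layer "loop" edges, {13,14}, {42,43} and {48,49}) under two
#' alternative sets of correlation strengths, called group 1 and group 2.
#' Reference high/medium/low classifications exist for outbreaks at region
#' 1 and at regions {1, 22} under thresholds (0.7, 0.4); the group-1
#' references are reproduced exactly by [epirisk()], while the group-2
#' level lists are internally inconsistent with the propagation rules that
#' reproduce group 1 and are shipped for information only (see the
#' vignette's discussion of this discrepancy).
#'
#' @param group 1 or 2.
#' @return `benchmark_network()`: a [risk_network()] with 50 nodes and 52
#'   weighted edges.
#' @export
#' @examples
#' bm <- benchmark_network(1)
#' bm
benchmark_network <- function(group = 1) {
  path <- benchmark_file(group, "edges.csv")
  read_edge_csv(path)
}

#' @rdname benchmark_network
#' @param case 1 (outbreak at region 1) or 2 (outbreaks at regions 1
#'   and 22).
#' @return `benchmark_expected()`: a list with `sources`, `thresholds`,
#'   `status` (`"reference"` or `"informational"`), and the `high`,
#'   `medium`, `low` region ID lists.
#' @export
benchmark_expected <- function(group = 1, case = 1) {
  if (!case %in% c(1, 2)) stop("`case` must be 1 or 2", call. = FALSE)
  path <- benchmark_file(group, sprintf("expected_case%d.json", case))
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  out$thresholds <- risk_thresholds(out$thresholds$p_s1, out$thresholds$p_s2)
  out
}

benchmark_file <- function(group, what) {
  if (!group %in% c(1, 2)) stop("`group` must be 1 or 2", call. = FALSE)
  path <- system.file("extdata", sprintf("group%d_%s", group, what),
                      package = "epirisknet")
  if (path == "")
    stop("bundled benchmark file not found: group", group, " ", what,
         call. = FALSE)
  path
}
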