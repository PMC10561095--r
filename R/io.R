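#' Read and write weighted edge lists
#'
#' The edge-list CSV format has header `source,target,weight`, one row per
#' undirected edge, weights written with at least four decimals so a
#' write/read round trip is lossless at the precision the correlation
#' function is reported at.
#'
#' @param path file path.
#' @return `read_edge_csv()`: a [risk_network()].
#' @export
read_edge_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("source", "target", "weight")
  if (!all(need %in% names(df)))
    stop(path, ": expected header `source,target,weight`", call. = FALSE)
  tryCatch(risk_network(df),
           error = function(e) stop(path, ": ", conditionMessage(e),
                                    call. = FALSE))
}

#' @rdname read_edge_csv
#' @param net a [risk_network()] or [orient_edges()] result; an oriented
#'   network is written with an extra `kind` column (`downhill`/`loop`).
#' @param digits decimals used for weights (default 6, minimum 4).
#' @export
write_edge_csv <- function(net, path, digits = 6) {
  stopifnot(inherits(net, "risk_network"))
  digits <- max(4L, as.integer(digits))
  fmt <- function(w) ifelse(is.na(w), "", formatC(w, digits = digits,
                                                  format = "f"))
  if (inherits(net, "oriented_network")) {
    a <- net$arcs
    out <- data.frame(source = a$from, target = a$to,
                      weight = fmt(a$weight), kind = a$kind)
  } else {
    e <- net$edges
    out <- data.frame(source = e$source, target = e$target,
                      weight = fmt(e$weight))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read indicator matrices from long-format CSV
#'
#' The long format has header `indicator,region_m,region_s,value`, one row
#' per indicator and ordered region pair. Every indicator must cover the
#' full `h x h` grid of region pairs.
#'
#' @param path file path.
#' @param directions named character vector mapping indicator names to
#'   `"proportional"`/`"inverse"`; unnamed indicators default to
#'   proportional, except an indicator named `distance` which defaults to
#'   inverse.
#' @return an [indicator_data()] object.
#' @export
read_indicator_csv <- function(path, directions = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("indicator", "region_m", "region_s", "value")
  if (!all(need %in% names(df)))
    stop(path, ": expected header `indicator,region_m,region_s,value`",
         call. = FALSE)
  regions <- sort(unique(c(df$region_m, df$region_s)))
  h <- length(regions)
  mats <- lapply(split(df, df$indicator), function(d) {
    B <- matrix(NA_real_, h, h)
    B[cbind(match(d$region_m, regions), match(d$region_s, regions))] <- d$value
    if (anyNA(B))
      stop(path, ": indicator ", d$indicator[1],
           " does not cover every region pair", call. = FALSE)
    B
  })
  dirs <- vapply(names(mats), function(nm) {
    if (!is.null(directions) && nm %in% names(directions)) directions[[nm]]
    else if (nm == "distance") "inverse" else "proportional"
  }, character(1))
  indicator_data(mats, dirs)
}

#' Write the artifacts of a fitted risk classification
#'
#' Writes `risk.tsv` (per-node layer, pre-loop and final risk value,
#' level), `report.json` (sources, thresholds, rounding, level lists and
#' counts, provenance hash) and, when a [critic_weights()] result is
#' supplied, `weights.json`.
#'
#' @param fit an [epirisk()] object.
#' @param dir output directory (created if needed).
#' @param critic optional `critic_result` whose weights should be saved.
#' @param config optional configuration list embedded (hashed) in the
#'   report for provenance.
#' @return invisibly, the paths written.
#' @export
write_report <- function(fit, dir, critic = NULL, config = NULL) {
  stopifnot(inherits(fit, "epirisk"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  tsv <- file.path(dir, "risk.tsv")
  utils::write.table(fit$values, tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  paths <- c(paths, tsv)

  report <- list(
    sources = fit$sources,
    thresholds = list(p_s1 = fit$thresholds$p_s1, p_s2 = fit$thresholds$p_s2),
    round_dp = fit$round_dp,
    levels = fit$report$levels,
    counts = as.list(fit$report$counts),
    # the hash covers the scientific configuration, not output locations
    config_hash = config_hash(config[setdiff(names(config), "out_dir")])
  )
  rj <- file.path(dir, "report.json")
  jsonlite::write_json(report, rj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  paths <- c(paths, rj)

  if (!is.null(critic)) {
    wj <- file.path(dir, "weights.json")
    jsonlite::write_json(as.list(critic$weights), wj, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths <- c(paths, wj)
  }
  invisible(paths)
}

# md5 of the canonical JSON serialisation of the config list
config_hash <- function(config) {
  if (is.null(config)) return(NULL)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full risk-classification pipeline from a configuration
#'
#' Ties the modules into one reproducible run. Two input modes exist:
#' `edges` (a ready-made weighted edge-list CSV) and `indicators` (raw
#' indicator data, long CSV, from which correlation strengths are derived
#' with CRITIC and attached to a network topology). The pipeline then
#' layers, orients, propagates and classifies, and optionally writes the
#' run artifacts.
#'
#' @param config a list (or path to a JSON file holding one) with fields:
#'   `mode` (`"edges"` or `"indicators"`); `edges` (path, mode `"edges"`);
#'   `indicators` (path) and either `topology` (edge-list CSV path, weights
#'   ignored) or `generator` (list `n_nodes`, `edges_per_new_node`, `seed`)
#'   for mode `"indicators"`; `sources` (vector of node IDs); optional
#'   `p_s1`, `p_s2`, `round_dp`, `directions`, `out_dir`.
#' @param verbose log each stage to `stderr` (default `FALSE`).
#' @return the [epirisk()] fit, invisibly if artifacts were written.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  say <- function(...) if (verbose) message("[epirisknet] ", ...)
  mode <- match.arg(config$mode, c("edges", "indicators"))
  critic <- NULL

  if (mode == "edges") {
    say("reading edge list: ", config$edges)
    net <- read_edge_csv(config$edges)
  } else {
    say("reading indicators: ", config$indicators)
    dirs <- unlist(config$directions)
    ind <- read_indicator_csv(config$indicators, directions = dirs)
    say("computing CRITIC weights over ", ind$t, " indicators")
    critic <- critic_weights(ind)
    if (!is.null(config$topology)) {
      say("attaching correlation strengths to topology: ", config$topology)
      topo <- read_edge_csv(config$topology)
    } else if (!is.null(config$generator)) {
      g <- config$generator
      say("generating scale-free topology (n = ", g$n_nodes, ")")
      topo <- generate_scale_free(g$n_nodes,
                                  g$edges_per_new_node %||% 1, g$seed)
    } else {
      stop("mode `indicators` needs either `topology` or `generator`",
           call. = FALSE)
    }
    net <- set_edge_weights(topo, critic$L)
  }

  th <- risk_thresholds(config$p_s1 %||% 0.7, config$p_s2 %||% 0.4)
  round_dp <- if (is.null(config$round_dp)) 2 else
    if (identical(config$round_dp, "none")) NULL else config$round_dp
  say("propagating risk from source(s): ",
      paste(config$sources, collapse = ", "))
  fit <- epirisk(net, config$sources, th, round_dp)
  say("levels: high ", fit$report$counts[["high"]],
      " / medium ", fit$report$counts[["medium"]],
      " / low ", fit$report$counts[["low"]])

  if (!is.null(config$out_dir)) {
    say("writing artifacts to ", config$out_dir)
    write_report(fit, config$out_dir, critic = critic, config = config)
    return(invisible(fit))
  }
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a
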