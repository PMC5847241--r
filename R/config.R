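#' Pipeline configuration
#'
#' Collects every tunable of the prediction pipeline with documented
#' defaults. All coordinates are 0-based half-open; scores are in duplex
#' alignment score units.
#'
#' @param L,W (L,W) pattern density: every window of `W` consecutive motif
#'   positions contains at least `L` literals. Defaults 4, 6.
#' @param min_support Minimum supporting sequences for a pattern; default
#'   `max(2, ceiling(0.01 * corpus size))` (resolved at run time when NULL).
#' @param markov_order Background Markov order (0-2), default 2.
#' @param significance_method `"inclusion"` (deterministic position-wise
#'   inclusion bound; default) or `"mc"` (Monte Carlo null).
#' @param n_null Number of Monte Carlo null corpora, default 1000.
#' @param min_log_odds Pattern significance threshold, default `log(2)`.
#' @param window Island window span (nt), default 25.
#' @param min_island_hits Minimum hit starts per window, default 5.
#' @param epsilon Equal-binding margin in score units, default 0.5: allele
#'   best scores within `epsilon` are called "equal".
#' @param maf_min Minor allele frequency cutoff (inclusive), default 0.03.
#' @param seed Seed for any stochastic stage (Monte Carlo null), default 1.
#' @param ... Passed to [duplex_params()] (`match_wc`, `match_gu`,
#'   `mismatch`, `gap_open`, `gap_extend`, `seed_min_pairs`,
#'   `min_report_score`, `wobble_in_seed`).
#' @return A `mirsnp_config` list.
#' @export
mirsnp_config <- function(L = 4L, W = 6L, min_support = NULL,
                          markov_order = 2L,
                          significance_method = c("inclusion", "mc"),
                          n_null = 1000L, min_log_odds = log(2),
                          window = 25L, min_island_hits = 5L,
                          epsilon = 0.5, maf_min = 0.03, seed = 1L, ...) {
  significance_method <- match.arg(significance_method)
  if (epsilon < 0) mirsnp_param_error("epsilon must be >= 0")
  structure(
    list(L = as.integer(L), W = as.integer(W),
         min_support = if (is.null(min_support)) NULL else as.integer(min_support),
         markov_order = as.integer(markov_order),
         significance_method = significance_method,
         n_null = as.integer(n_null), min_log_odds = min_log_odds,
         window = as.integer(window),
         min_island_hits = as.integer(min_island_hits),
         epsilon = epsilon, maf_min = maf_min, seed = as.integer(seed),
         duplex = duplex_params(...)),
    class = "mirsnp_config"
  )
}

#' @export
print.mirsnp_config <- function(x, ...) {
  cat("<mirsnp_config>\n")
  for (nm in setdiff(names(x), "duplex")) {
    cat(sprintf("  %s = %s\n", nm,
                if (is.null(x[[nm]])) "auto" else format(x[[nm]])))
  }
  for (nm in names(x$duplex)) {
    cat(sprintf("  duplex.%s = %s\n", nm, format(x$duplex[[nm]])))
  }
  invisible(x)
}

# Flat key=value config file support for the CLI; duplex.* keys address the
# alignment parameters.
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- stringi::stri_match_first_regex(lines, "^\\s*([A-Za-z_.]+)\\s*[=:]\\s*(.*?)\\s*$")
  if (any(is.na(kv[, 1]))) {
    mirsnp_input_error(sprintf("cannot parse config line: %s",
                               lines[which(is.na(kv[, 1]))[1]]))
  }
  vals <- as.list(kv[, 3])
  names(vals) <- kv[, 2]
  vals <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num
    else if (toupper(v) %in% c("TRUE", "FALSE")) as.logical(toupper(v))
    else v
  })
  dux <- startsWith(names(vals), "duplex.")
  args <- vals[!dux]
  names(vals)[dux] <- sub("^duplex\\.", "", names(vals)[dux])
  do.call(mirsnp_config, c(args, vals[dux]))
}

config_echo_lines <- function(config) {
  flat <- c(config[setdiff(names(config), "duplex")],
            setNames(config$duplex, paste0("duplex.", names(config$duplex))))
  vapply(names(flat), function(nm) {
    sprintf("%s=%s", nm,
            if (is.null(flat[[nm]])) "auto" else format(flat[[nm]], digits = 15))
  }, character(1))
}
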