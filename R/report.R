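PKG_VERSION <- function()
  as.character(utils::packageVersion("csrdesign"))

required_design_fields <- c("r_nul", "r_alt", "ttp_nul", "ttp_alt", "n1", "n2")
optional_config_fields <- c("t_first", "censor_prob", "min_median_ttp",
                            "alpha_max", "power_min", "n_sim",
                            "ttp_grid_step", "seed")

#' Read a design configuration file
#'
#' Flat YAML or JSON with snake_case keys named exactly as the
#' [csr_hypotheses()] / [csr_config()] fields. Values given in `overrides`
#' (e.g. from CLI flags) replace file values.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` to use
#'   `overrides` alone.
#' @param overrides Named list of field overrides.
#' @return A named list of configuration values.
#' @export
read_design_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_invalid(sprintf("config file '%s' not found", path))
    vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    else
      yaml::read_yaml(path)
    if (!is.list(vals)) stop_invalid("config file must contain a mapping of fields")
  }
  vals[names(overrides)] <- overrides
  vals
}

split_design_inputs <- function(vals) {
  missing <- setdiff(required_design_fields, names(vals))
  if (length(missing) > 0)
    stop_invalid(sprintf("missing required config field(s): %s",
                         paste(missing, collapse = ", ")))
  unknown <- setdiff(names(vals),
                     c(required_design_fields, optional_config_fields))
  if (length(unknown) > 0)
    stop_invalid(sprintf("unknown config field(s): %s",
                         paste(unknown, collapse = ", ")))
  cfg_args <- vals[intersect(names(vals), optional_config_fields)]
  cfg <- do.call(csr_config, c(list(n1 = vals$n1, n2 = vals$n2), cfg_args))
  hyp <- csr_hypotheses(vals$r_nul, vals$r_alt, vals$ttp_nul, vals$ttp_alt,
                        t_first = cfg$t_first)
  list(hypotheses = hyp, config = cfg)
}

#' Build the serialisable report for a derived design
#'
#' @param design A `"csr_design"` from [design_csr()].
#' @return A plain list (class `"csr_report"`) echoing the inputs and
#'   carrying the rules, operating characteristics with their Monte-Carlo
#'   standard errors, package version, seed and timestamp.
#' @export
design_report <- function(design) {
  stopifnot(inherits(design, "csr_design"))
  structure(list(
    inputs = list(
      hypotheses = unclass(design$hypotheses),
      config = unclass(design$config)
    ),
    rules = unclass(design$rules),
    oc = unclass(design$oc),
    stage2 = design$stage2,
    relaxed = design$relaxed,
    seed = design$config$seed,
    version = PKG_VERSION(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "csr_report")
}

#' @rdname design_report
#' @param report A `"csr_report"`.
#' @param path Output file path.
#' @export
write_design_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname design_report
#' @export
read_design_report <- function(path) {
  structure(jsonlite::fromJSON(path, simplifyVector = TRUE),
            class = "csr_report")
}

#' One CSV row per design, in design-table column order
#'
#' Column order follows the conventional design-table layout: hypothesis
#' parameters, stage sizes, the four thresholds, then power, alpha, and
#' the null/alternative expected sample size and early-stopping pairs.
#'
#' @param design A `"csr_design"`.
#' @return A one-row `data.frame`.
#' @export
design_csv_row <- function(design) {
  h <- design$hypotheses; cfg <- design$config
  r <- design$rules; oc <- design$oc
  data.frame(
    r_nul = h$r_nul, r_alt = h$r_alt,
    ttp_nul = h$ttp_nul, ttp_alt = h$ttp_alt,
    n1 = cfg$n1, n2 = cfg$n2,
    r1_stop = r$r1_stop, epd_stop = r$epd_stop,
    r2_reject = r$r2_reject, ttp2_reject = r$ttp2_reject,
    power = oc$power, alpha = oc$alpha,
    en_nul = oc$en_nul, pes_nul = oc$pes_nul,
    en_alt = oc$en_alt, pes_alt = oc$pes_alt
  )
}

#' Run a full design derivation from a configuration
#'
#' High-level driver behind the command-line interface: reads the
#' configuration, derives the design with [design_csr()], and optionally
#' writes the JSON report and the design-table CSV row.
#'
#' @param config_file Path to a YAML/JSON configuration file (or `NULL`).
#' @param overrides Named list overriding file values (CLI flags).
#' @param out_json,out_csv Optional output paths.
#' @param quiet Suppress progress messages.
#' @return The `"csr_report"`, invisibly; the derived `"csr_design"` is
#'   attached as attribute `"design"`.
#' @export
run_design <- function(config_file = NULL, overrides = list(),
                       out_json = NULL, out_csv = NULL, quiet = FALSE) {
  inp <- split_design_inputs(read_design_config(config_file, overrides))
  if (!quiet) {
    message(sprintf("hypotheses: RR %g vs %g, median TTP %g vs %g mo (EPD %0.4f vs %0.4f at t_first = %g)",
                    inp$hypotheses$r_nul, inp$hypotheses$r_alt,
                    inp$hypotheses$ttp_nul, inp$hypotheses$ttp_alt,
                    inp$hypotheses$epd_nul, inp$hypotheses$epd_alt,
                    inp$hypotheses$t_first))
    message(sprintf("searching %d response thresholds x %d TTP thresholds over %d simulated trials per bank (seed %s)",
                    inp$config$n1 + inp$config$n2,
                    length(ttp_grid(inp$hypotheses, inp$config)),
                    inp$config$n_sim,
                    if (is.null(inp$config$seed)) "unset" else inp$config$seed))
  }
  t0 <- proc.time()[["elapsed"]]
  design <- design_csr(inp$hypotheses, inp$config)
  if (!quiet)
    message(sprintf("design derived in %.1f s", proc.time()[["elapsed"]] - t0))
  report <- design_report(design)
  if (!is.null(out_json)) write_design_report(report, out_json)
  if (!is.null(out_csv))
    utils::write.csv(design_csv_row(design), out_csv, row.names = FALSE)
  attr(report, "design") <- design
  invisible(report)
}

#' Derive designs for a batch of hypothesis rows
#'
#' Runs [design_csr()] once per row and aggregates the design-table CSV
#' rows. A failing row is logged and marked, not fatal.
#'
#' @param rows A `data.frame` (or list of named lists), one design per row,
#'   with at least the fields `r_nul`, `r_alt`, `ttp_nul`, `ttp_alt`;
#'   missing fields fall back to `defaults`.
#' @param defaults Named list of shared fields (e.g. `n1`, `n2`, `n_sim`,
#'   `seed`).
#' @param out_csv Optional path for the aggregated CSV.
#' @param quiet Suppress progress messages.
#' @return A `data.frame` of design rows with a `status` column
#'   (`"ok"` or the error message).
#' @export
run_table <- function(rows, defaults = list(), out_csv = NULL, quiet = FALSE) {
  if (is.data.frame(rows)) rows <- split(rows, seq_len(nrow(rows)))
  if (length(rows) == 0L) stop_invalid("batch contains no design rows")
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    vals <- utils::modifyList(defaults, as.list(rows[[i]]))
    out[[i]] <- tryCatch({
      inp <- split_design_inputs(vals)
      d <- design_csr(inp$hypotheses, inp$config)
      cbind(design_csv_row(d), status = "ok")
    }, error = function(e) {
      if (!quiet) message(sprintf("row %d failed: %s", i, conditionMessage(e)))
      row <- as.data.frame(vals[intersect(names(vals), required_design_fields)])
      empty <- design_csv_row_template()
      empty[names(row)] <- row
      cbind(empty, status = conditionMessage(e))
    })
    if (!quiet && identical(out[[i]]$status, "ok"))
      message(sprintf("row %d: rules (<= %d, >= %d | >= %d, >= %.2f), power %.3f, alpha %.3f",
                      i, out[[i]]$r1_stop, out[[i]]$epd_stop,
                      out[[i]]$r2_reject, out[[i]]$ttp2_reject,
                      out[[i]]$power, out[[i]]$alpha))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(out_csv)) utils::write.csv(res, out_csv, row.names = FALSE)
  res
}

design_csv_row_template <- function() {
  data.frame(r_nul = NA_real_, r_alt = NA_real_, ttp_nul = NA_real_,
             ttp_alt = NA_real_, n1 = NA_integer_, n2 = NA_integer_,
             r1_stop = NA_integer_, epd_stop = NA_integer_,
             r2_reject = NA_integer_, ttp2_reject = NA_real_,
             power = NA_real_, alpha = NA_real_, en_nul = NA_real_,
             pes_nul = NA_real_, en_alt = NA_real_, pes_alt = NA_real_)
}
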