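md_table <- function(df, digits = 4) {
  fmt <- function(x) {
    if (is.numeric(x)) {
      formatC(x, digits = digits, format = "g")
    } else {
      as.character(x)
    }
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

read_output_csv <- function(dir, name, required_cols) {
  path <- file.path(dir, paste0(name, ".csv"))
  if (!file.exists(path)) return(NULL)
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE),
    error = function(e) rlang::abort(paste0("cannot parse ", path, ": ",
                                            conditionMessage(e)))
  )
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    rlang::abort(paste0(path, " is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  df
}

#' Render a plain-text report from pipeline outputs
#'
#' Reads the CSVs written by [run_pipeline()] and assembles a single
#' markdown report: the consumption/sugar/energy impacts, the weight-change
#' block, the prevalence table, the diabetes burden, and (when present) the
#' Monte Carlo and elasticity sensitivity-analysis appendices. Missing
#' tables are listed as absent rather than failing.
#'
#' @param out_dir Directory containing the pipeline outputs.
#' @param file Optional path for the rendered report; defaults to
#'   `report.md` inside `out_dir`.
#' @return The report text, invisibly, as a character vector of lines.
#' @export
render_report <- function(out_dir, file = file.path(out_dir, "report.md")) {
  if (!dir.exists(out_dir)) rlang::abort(paste0("no such output directory: ", out_dir))
  lines <- c("# SSB tax health-impact report", "")

  section <- function(title, name, cols, note = NULL) {
    df <- read_output_csv(out_dir, name, cols)
    out <- c(paste0("## ", title), "")
    if (is.null(df)) {
      out <- c(out, paste0("_Table `", name, ".csv` is absent._"), "")
    } else {
      out <- c(out, md_table(df), "")
      if (!is.null(note)) out <- c(out, note, "")
    }
    out
  }

  lines <- c(
    lines,
    section("Consumption, sugar and energy impacts", "market_impact",
            c("scenario_id", "price_increase", "dvolume_total")),
    section("Weight change (kg, equilibrium reductions)", "weight_change",
            c("scenario_id", "group", "weight_reduction_kg")),
    section("Overweight and obesity prevalence", "prevalence",
            c("scenario_id", "class", "stratum", "estimate")),
    section("Type-2-diabetes burden", "burden",
            c("scenario_id", "stratum", "dbmi"))
  )
  mc <- read_output_csv(out_dir, "mc_summary",
                        c("scenario_id", "model", "output", "mean", "sd"))
  if (is.null(mc)) {
    lines <- c(lines, "## Uncertainty", "",
               "_Monte Carlo summary absent: deterministic-only run._", "")
  } else {
    lines <- c(lines, "## Uncertainty (Monte Carlo)", "", md_table(mc), "")
  }
  lines <- c(
    lines,
    section("Sensitivity analysis: price elasticity", "sa_elasticity",
            c("elasticity", "scenario_id", "dvolume_total"))
  )
  writeLines(lines, file)
  invisible(lines)
}
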