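#' Read a long-format observation table
#'
#' Parses a delimited text file with one row per observation: a group
#' label, a numeric value, and optionally a variable (feature) name so that
#' several measured quantities can share one file.  Rows with non-finite
#' values are dropped with a message; a non-numeric entry in the value
#' column is an error naming the offending row.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param delimiter `"auto"` (sniffed from the header line), `"comma"` or
#'   `"tab"`.
#' @param group_col,value_col Column names holding the group label and the
#'   numeric value.
#' @param variable_col Optional column naming the measured variable; when
#'   `NULL` all rows belong to the single variable `"value"`.
#' @return An object of class `long_table`: data frame with columns
#'   `group`, `variable`, `value`.
#' @export
read_long_table <- function(path, delimiter = c("auto", "comma", "tab"),
                            group_col = "group", value_col = "value",
                            variable_col = NULL) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) stop("file not found: ", path)
  if (delimiter == "auto") {
    header <- readLines(path, n = 1L)
    delimiter <- if (grepl("\t", header)) "tab" else "comma"
  }
  sep <- if (delimiter == "tab") "\t" else ","
  raw <- read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", quote = "\"")
  need <- c(group_col, value_col, variable_col)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L)
    stop("schema error: column(s) ", paste(missing_cols, collapse = ", "),
         " not found; available: ", paste(names(raw), collapse = ", "))
  vals <- suppressWarnings(as.numeric(raw[[value_col]]))
  unparsed <- is.na(vals) & !(trimws(toupper(raw[[value_col]])) %in%
                                c("NA", "NAN", ""))
  if (any(unparsed))
    stop("parse error: non-numeric value in column '", value_col,
         "' at data row ", which(unparsed)[1])
  tab <- data.frame(
    group = trimws(raw[[group_col]]),
    variable = if (is.null(variable_col)) "value" else
      trimws(raw[[variable_col]]),
    value = vals,
    stringsAsFactors = FALSE)
  bad <- !is.finite(tab$value) | !nzchar(tab$group)
  if (any(bad)) {
    message("read_long_table: dropped ", sum(bad),
            " row(s) with non-finite values or empty group labels")
    tab <- tab[!bad, , drop = FALSE]
  }
  if (length(unique(tab$group)) < 2L)
    stop("insufficient groups: need at least 2 distinct groups")
  class(tab) <- c("long_table", "data.frame")
  tab
}

#' Compare all group pairs of a long table
#'
#' For each variable of the table and each unordered pair of groups, runs
#' the full pipeline (MCCV, exponential fit, decision calculus) and returns
#' one comparison report per pair.  The sampling grid is capped per pair at
#' the smaller group size; pairs with a group of fewer than 2 observations
#' (or below `n_min`) are skipped with a message rather than failing the
#' whole run.  Reports are ordered by variable, then by the pair labels.
#'
#' @param table A [read_long_table()] result (or data frame with columns
#'   `group`, `variable`, `value`).
#' @param config A [decision_config()].
#' @param n_min,n_max,num_sizes,rep_max,rep_min Grid parameters, passed to
#'   [build_grid()] with `n_max` capped at the smaller group size of each
#'   pair.
#' @param test,tail_mode,exact,fit_space Pipeline options (defaults: the
#'   calibrated study profile).
#' @param seed Master seed; one derived seed per comparison.
#' @return List of `comparison_report` objects; each is a one-row data
#'   frame (the [decide()] report plus identification, test settings and
#'   seed echo), with the fitted model and cloud summaries attached as
#'   attributes.
#' @export
pairwise_compare <- function(table, config = decision_config(),
                             n_min = 2, n_max = 2500, num_sizes = 30,
                             rep_max = 500, rep_min = 20,
                             test = "mann_whitney",
                             tail_mode = "folded_one_sided",
                             exact = FALSE,
                             fit_space = "linear",
                             seed = 1L) {
  stopifnot(is.data.frame(table),
            all(c("group", "variable", "value") %in% names(table)))
  variables <- sort(unique(table$variable))
  combos <- list()
  for (v in variables) {
    groups <- sort(unique(table$group[table$variable == v]))
    if (length(groups) < 2L) next
    for (i in seq_len(length(groups) - 1L))
      for (j in (i + 1L):length(groups))
        combos[[length(combos) + 1L]] <- c(v, groups[i], groups[j])
  }
  seeds <- derive_seeds(seed, max(1L, length(combos)))
  reports <- list()
  for (k in seq_along(combos)) {
    v <- combos[[k]][1]; ga <- combos[[k]][2]; gb <- combos[[k]][3]
    xa <- table$value[table$variable == v & table$group == ga]
    xb <- table$value[table$variable == v & table$group == gb]
    cap <- min(length(xa), length(xb))
    if (cap < max(2, n_min)) {
      message("pairwise_compare: skipping ", v, ": ", ga, " vs ", gb,
              " (a group has fewer than ", max(2, n_min), " observations)")
      next
    }
    grid <- build_grid(n_min, min(n_max, cap), num_sizes, rep_max, rep_min)
    cloud <- run_mccv(observation_group(ga, xa), observation_group(gb, xb),
                      grid, test = test, tail_mode = tail_mode,
                      seed = seeds[k], exact = exact)
    model <- fit_exponential(cloud, fit_space)
    rep <- decide(model, cloud, config)
    out <- cbind(data.frame(variable = v, group_a = ga, group_b = gb,
                            n_a = length(xa), n_b = length(xb),
                            test = test, tail_mode = tail_mode,
                            fit_space = fit_space,
                            stringsAsFactors = FALSE),
                 as.data.frame(rep),
                 data.frame(alpha = config$alpha, gamma = config$gamma,
                            seed = seeds[k]))
    attr(out, "model") <- model
    attr(out, "summaries") <- cloud$summaries
    class(out) <- c("comparison_report", "data.frame")
    reports[[length(reports) + 1L]] <- out
  }
  reports
}

#' Flatten comparison reports to one table
#'
#' @param reports List of reports from [pairwise_compare()].
#' @return Data frame with one row per comparison.
#' @export
reports_to_table <- function(reports) {
  if (length(reports) == 0L) {
    return(data.frame(variable = character(), group_a = character(),
                      group_b = character()))
  }
  do.call(rbind, lapply(reports, function(r) {
    r <- as.data.frame(r)
    class(r) <- "data.frame"
    r
  }))
}

#' Write comparison reports to disk
#'
#' Writes a nested JSON report (full precision, config echo, package
#' version) and/or a flat CSV with one row per comparison.  Non-finite
#' numbers are encoded with the sentinel string `"inf"` and undefined
#' quantities (no-decay path) with `"no_decay"`, so the CSV loads cleanly
#' in standard tools.
#'
#' @param reports List of reports from [pairwise_compare()] (a
#'   `study_result` is also accepted and flattened).
#' @param out_dir Output directory, created if needed.
#' @param formats Subset of `c("json", "csv")`.
#' @param stem File name stem (default "comparisons").
#' @return Invisibly, the paths written.
#' @export
write_report <- function(reports, out_dir, formats = c("json", "csv"),
                         stem = "comparisons") {
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  tab <- if (is.data.frame(reports)) as.data.frame(reports) else
    reports_to_table(reports)
  if (nrow(tab) == 0L) message("write_report: empty report collection")
  paths <- character(0)
  if ("csv" %in% formats) {
    ctab <- tab
    for (col in names(ctab)) {
      if (is.numeric(ctab[[col]])) {
        v <- format(ctab[[col]], digits = 17, trim = TRUE, scientific = NA)
        v[is.infinite(ctab[[col]])] <- "inf"
        v[is.na(ctab[[col]])] <- "no_decay"
        ctab[[col]] <- v
      }
    }
    f <- file.path(out_dir, paste0(stem, ".csv"))
    write.csv(ctab, f, row.names = FALSE)
    paths <- c(paths, f)
  }
  if ("json" %in% formats) {
    payload <- list(
      tool = "pndecay",
      version = as.character(packageVersion("pndecay")),
      n_comparisons = nrow(tab),
      comparisons = tab)
    f <- file.path(out_dir, paste0(stem, ".json"))
    jsonlite::write_json(payload, f, auto_unbox = TRUE, digits = NA,
                         na = "string", pretty = TRUE)
    paths <- c(paths, f)
  }
  invisible(paths)
}
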