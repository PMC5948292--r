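PANEL_COLUMNS <- c("person_id", "base_year_index", "age", "sex", "ethnicity",
                   "urbanization", "pcg", "dcg", "basic_claims", "supp_claims")

#' Read / write an insured claims panel as CSV
#'
#' The on-disk format is one row per person-year with the canonical column
#' set (`person_id`, `base_year_index`, `age`, `sex`, `ethnicity`,
#' `urbanization`, `pcg`, `dcg`, `basic_claims`, `supp_claims`), UTF-8,
#' `.` decimal separator. `write_panel()` followed by `read_panel()` is the
#' identity on valid panels.
#'
#' @param path CSV file path.
#' @param panel an `insured_panel`.
#' @return `read_panel()` returns an `insured_panel`; `write_panel()` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(PANEL_COLUMNS, names(df))
  if (length(missing))
    stop("panel file is missing required columns: ",
         paste(missing, collapse = ", "))
  df <- df[PANEL_COLUMNS]
  for (col in c("basic_claims", "supp_claims", "age", "base_year_index")) {
    if (!is.numeric(df[[col]]))
      stop(sprintf("panel column '%s' must be numeric", col))
  }
  if (any(df$supp_claims < 0) || any(df$basic_claims < 0))
    stop("panel claims must be non-negative")
  if (any(df$age < 18))
    stop("panel contains insured younger than 18 (adults only)")
  df$pcg <- as.logical(df$pcg)
  df$dcg <- as.logical(df$dcg)
  years <- sort(unique(df$base_year_index))
  n_years <- length(years)
  if (!identical(as.integer(years), 0:(n_years - 1L)))
    stop("base_year_index must cover 0..", n_years - 1L, " without gaps")
  tab <- table(df$person_id)
  if (any(tab != n_years))
    stop("unbalanced panel: every person must have exactly one record per ",
         "base year; offending person(s): ",
         paste(head(names(tab)[tab != n_years], 5), collapse = ", "))
  per_person_years <- tapply(df$base_year_index, df$person_id,
                             function(y) length(unique(y)))
  if (any(per_person_years != n_years))
    stop("unbalanced panel: duplicated person-year records")
  df <- df[order(df$person_id, df$base_year_index), ]
  rownames(df) <- NULL
  as_insured_panel(df, n_individuals = length(tab),
                   n_base_years = n_years - 1L)
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "insured_panel"))
  out <- as.data.frame(panel)
  # 17 significant digits guarantee an exact double round trip
  for (col in c("basic_claims", "supp_claims"))
    out[[col]] <- sprintf("%.17g", out[[col]])
  write.csv(out, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}
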