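# Participant CSV schema: one row per woman, '.' decimal separator, UTF-8.
# Categorical vocabularies are fixed so files round-trip to identical
# analysis factors ("Unknown" is an admissible level everywhere).
participant_schema <- function() {
  list(
    required = c("id", "status", "age_mammogram", "bmi", "region",
                 "insurance", "financial_screen", "education", "ethnicity",
                 "tc10", "vpd", "fibro_volume", "fat_volume", "birads"),
    levels = list(
      status = c("control", "case"),
      region = c("primary", "outlying"),
      insurance = c("insured", "medicaid", "none"),
      financial_screen = c("never", "ever"),
      education = c("more", "less"),
      ethnicity = c("white", "other")
    )
  )
}

#' Read a participant table from CSV
#'
#' Reads and validates the participant schema: required columns, categorical
#' vocabularies, `birads` in 1--4, `vpd` in (0, 100), positive `tc10`,
#' non-negative volumes. Row-level problems are reported with their file
#' line numbers; if more than 10% of data rows are invalid the read aborts,
#' otherwise invalid rows are dropped with a warning.
#'
#' @param path CSV file with a header row.
#' @return Validated `data.frame` with typed columns.
#' @export
read_participants <- function(path) {
  sc <- participant_schema()
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(sc$required, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("read_participants: missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(tab) == 0) {
    for (v in names(sc$levels)) tab[[v]] <- factor(tab[[v]], levels = c(sc$levels[[v]], "Unknown"))
    return(tab)
  }
  problems <- character(0)
  bad <- rep(FALSE, nrow(tab))
  note <- function(rows, msg) {
    if (any(rows)) {
      problems <<- c(problems,
                     sprintf("line %d: %s", which(rows) + 1L, msg))
      bad <<- bad | rows
    }
  }
  for (v in names(sc$levels)) {
    lv <- c(sc$levels[[v]], "Unknown")
    note(!(tab[[v]] %in% lv) & !is.na(tab[[v]]),
         sprintf("invalid %s (allowed: %s)", v, paste(lv, collapse = "/")))
  }
  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  for (v in c("age_mammogram", "bmi", "tc10", "vpd",
              "fibro_volume", "fat_volume", "birads")) {
    tab[[v]] <- num_or_na(tab[[v]])
  }
  note(!is.finite(tab$age_mammogram), "non-numeric age_mammogram")
  note(is.finite(tab$bmi) & tab$bmi <= 0 | !is.finite(tab$bmi), "bmi must be > 0")
  note(!is.finite(tab$tc10) | tab$tc10 <= 0, "tc10 must be > 0")
  note(!is.finite(tab$vpd) | tab$vpd <= 0 | tab$vpd >= 100,
       "vpd must lie in (0, 100)")
  note(!is.finite(tab$birads) | !(tab$birads %in% 1:4),
       "birads must be an integer in 1..4")
  note(is.finite(tab$fibro_volume) & tab$fibro_volume < 0, "negative fibro_volume")
  note(is.finite(tab$fat_volume) & tab$fat_volume < 0, "negative fat_volume")
  if (length(problems)) {
    shown <- paste(head(problems, 10), collapse = "; ")
    if (mean(bad) > 0.10) {
      stop(sprintf("read_participants: %d of %d rows invalid (> 10%%): %s",
                   sum(bad), nrow(tab), shown), call. = FALSE)
    }
    warning(sprintf("read_participants: dropped %d invalid row(s): %s",
                    sum(bad), shown))
    tab <- tab[!bad, , drop = FALSE]
  }
  for (v in names(sc$levels)) {
    lv <- c(sc$levels[[v]], if ("Unknown" %in% tab[[v]]) "Unknown")
    tab[[v]] <- factor(tab[[v]], levels = lv)
  }
  tab$birads <- as.integer(tab$birads)
  tab
}

#' Write a participant table to CSV
#'
#' @param tab participant table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(tab, path) {
  sc <- participant_schema()
  write.csv(tab[, intersect(c(sc$required), names(tab)), drop = FALSE],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a square cross-tabulation of counts from CSV
#'
#' Expects a header row of column labels and a first column of row labels.
#'
#' @param path CSV file.
#' @return Numeric count matrix with dimnames.
#' @export
read_crosstab <- function(path) {
  tab <- read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(tab)
  storage.mode(m) <- "numeric"
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("read_crosstab: counts must be non-negative numbers", call. = FALSE)
  }
  m
}
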