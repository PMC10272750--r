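#' Read a twin cohort from a subject-level CSV file
#'
#' The canonical input is one row per subject (long format) with columns for
#' the subject identifier, pair identifier, zygosity, sex, age in years, and
#' one column per measured protein (ng/mL). Pair-level (wide) data are derived
#' with [to_pair_observations()], never stored.
#'
#' Zygosity codes `"MZ"`/`"DZ"` are accepted case-insensitively; sex codes may
#' be `"M"`/`"F"` or `"male"`/`"female"` (any case). Empty phenotype cells
#' become `NA`, never zero.
#'
#' @param path Path to a CSV file (UTF-8, comma-separated, header row).
#' @param proteins Character vector of protein column names. Defaults to every
#'   column not claimed by the identifier/demographic columns.
#' @param columns Named list mapping the roles `subject_id`, `pair_id`,
#'   `zygosity`, `sex`, `age` to column names in the file. Partial lists are
#'   merged over the defaults (which use the role names themselves).
#' @return A `twin_cohort`: a data frame with columns `subject_id`, `pair_id`,
#'   `zygosity` (factor, MZ/DZ), `sex` (factor, female/male), `age`, and one
#'   numeric column per protein, plus a `proteins` attribute. Row order is the
#'   file order.
#' @seealso [validate_cohort()], [to_pair_observations()]
#' @export
read_cohort <- function(path, proteins = NULL, columns = list()) {
  if (!file.exists(path)) {
    stop("cohort file not found: ", path)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- utils::modifyList(
    list(subject_id = "subject_id", pair_id = "pair_id",
         zygosity = "zygosity", sex = "sex", age = "age"),
    columns
  )
  missing_cols <- setdiff(unlist(cols), names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(proteins)) {
    proteins <- setdiff(names(raw), unlist(cols))
  } else {
    unknown <- setdiff(proteins, names(raw))
    if (length(unknown) > 0) {
      stop("protein column(s) not in file: ", paste(unknown, collapse = ", "))
    }
  }
  df <- data.frame(
    subject_id = as.character(raw[[cols$subject_id]]),
    pair_id    = as.character(raw[[cols$pair_id]]),
    zygosity   = as.character(raw[[cols$zygosity]]),
    sex        = as.character(raw[[cols$sex]]),
    age        = as.numeric(raw[[cols$age]]),
    stringsAsFactors = FALSE
  )
  for (p in proteins) {
    df[[p]] <- suppressWarnings(as.numeric(raw[[p]]))
  }
  if (nrow(df) > 0) {
    zyg <- toupper(trimws(df$zygosity))
    bad <- which(!zyg %in% c("MZ", "DZ"))
    if (length(bad) > 0) {
      stop("unparsable zygosity code ", shQuote(df$zygosity[bad[1]]),
           " in data row ", bad[1])
    }
    sex <- .parse_sex(df$sex)
    bad <- which(is.na(sex))
    if (length(bad) > 0) {
      stop("unparsable sex code ", shQuote(df$sex[bad[1]]),
           " in data row ", bad[1])
    }
    dup <- df$subject_id[duplicated(df$subject_id)]
    if (length(dup) > 0) {
      stop("duplicate subject_id: ", paste(unique(dup), collapse = ", "))
    }
    df$zygosity <- zyg
    df$sex <- sex
  }
  new_twin_cohort(df, proteins)
}

.parse_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("m", "male")] <- "male"
  out[x %in% c("f", "female")] <- "female"
  out
}

#' Construct a twin cohort from a subject-level data frame
#'
#' @param subjects Data frame with columns `subject_id`, `pair_id`,
#'   `zygosity`, `sex`, `age` and one column per protein.
#' @param proteins Character vector naming the protein columns.
#' @return A `twin_cohort` object.
#' @export
new_twin_cohort <- function(subjects, proteins) {
  stopifnot(is.data.frame(subjects))
  req <- c("subject_id", "pair_id", "zygosity", "sex", "age")
  missing_cols <- setdiff(c(req, proteins), names(subjects))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  subjects$zygosity <- factor(as.character(subjects$zygosity), c("MZ", "DZ"))
  subjects$sex <- factor(as.character(subjects$sex), c("female", "male"))
  rownames(subjects) <- NULL
  structure(subjects[, c(req, proteins), drop = FALSE],
            proteins = proteins,
            class = c("twin_cohort", "data.frame"))
}

#' Protein names carried by a cohort
#' @param cohort A `twin_cohort`.
#' @return Character vector of protein column names.
#' @export
cohort_proteins <- function(cohort) attr(cohort, "proteins")

#' @export
print.twin_cohort <- function(x, ...) {
  cat(sprintf("twin cohort: %d subjects, %d pair ids (%d MZ / %d DZ subjects)\n",
              nrow(x), length(unique(x$pair_id)),
              sum(x$zygosity == "MZ"), sum(x$zygosity == "DZ")))
  cat("proteins:", paste(cohort_proteins(x), collapse = ", "), "\n")
  invisible(x)
}

#' Check a cohort against the twin-design invariants
#'
#' Reported rules: each `pair_id` occurs at most twice; both members of a pair
#' share zygosity and sex (the design admits same-sex pairs only); ages are
#' positive; phenotype values present are finite and non-negative.
#'
#' @param cohort A `twin_cohort`.
#' @return A data frame with columns `pair_id` and `rule`, one row per
#'   violation; zero rows when the cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  violations <- list()
  add <- function(pair_id, rule) {
    violations[[length(violations) + 1]] <<- data.frame(
      pair_id = pair_id, rule = rule, stringsAsFactors = FALSE)
  }
  tab <- table(cohort$pair_id)
  for (pid in names(tab)[tab > 2]) {
    add(pid, sprintf("pair_id occurs %d times (max 2)", tab[[pid]]))
  }
  for (pid in unique(cohort$pair_id)) {
    rows <- cohort[cohort$pair_id == pid, ]
    if (length(unique(as.character(rows$zygosity))) > 1) {
      add(pid, "members differ in zygosity")
    }
    if (length(unique(as.character(rows$sex))) > 1) {
      add(pid, "members differ in sex (same-sex design)")
    }
    if (any(!is.na(rows$age) & rows$age <= 0) || any(is.na(rows$age))) {
      add(pid, "age missing or not positive")
    }
    for (p in cohort_proteins(cohort)) {
      v <- rows[[p]]
      if (any(!is.na(v) & (!is.finite(v) | v < 0))) {
        add(pid, sprintf("%s has non-finite or negative value", p))
      }
    }
  }
  if (length(violations) == 0) {
    return(data.frame(pair_id = character(), rule = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, violations)
}

#' Reshape a cohort into intact pair observations for one protein
#'
#' Only intact pairs enter twin analyses: a pair contributes one observation
#' when both members are present and both have a non-missing value for the
#' requested protein. Within-pair member order follows the input row order.
#'
#' @param cohort A `twin_cohort`.
#' @param protein Name of one protein column.
#' @param quiet Suppress the message reporting dropped pairs.
#' @return Data frame of class `pair_observations` with columns `pair_id`,
#'   `zygosity`, `sex`, `age1`, `age2`, `y1`, `y2`; attribute `n_dropped`
#'   records how many pairs were dropped for missingness.
#' @export
to_pair_observations <- function(cohort, protein, quiet = FALSE) {
  if (!protein %in% cohort_proteins(cohort)) {
    stop("unknown protein: ", protein)
  }
  n <- nrow(cohort)
  pid <- cohort$pair_id
  n_pairs_total <- length(unique(pid))
  if (n > 0) {
    fid <- factor(pid, levels = unique(pid))   # first-occurrence order
    cnt <- stats::ave(rep(1L, n), fid, FUN = length)
    mem <- stats::ave(seq_len(n), fid, FUN = seq_along)
    i1 <- which(cnt == 2L & mem == 1L)
    i2_all <- which(mem == 2L)
    i2 <- i2_all[match(pid[i1], pid[i2_all])]
    y1 <- cohort[[protein]][i1]
    y2 <- cohort[[protein]][i2]
    ok <- !is.na(y1) & !is.na(y2)
    out <- data.frame(
      pair_id = pid[i1][ok],
      zygosity = as.character(cohort$zygosity)[i1][ok],
      sex = as.character(cohort$sex)[i1][ok],
      age1 = cohort$age[i1][ok], age2 = cohort$age[i2][ok],
      y1 = y1[ok], y2 = y2[ok],
      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(pair_id = character(), zygosity = character(),
                      sex = character(), age1 = numeric(), age2 = numeric(),
                      y1 = numeric(), y2 = numeric(), stringsAsFactors = FALSE)
  }
  n_dropped <- n_pairs_total - nrow(out)
  if (!quiet && n_dropped > 0) {
    message(sprintf("%s: dropped %d incomplete pair(s)", protein, n_dropped))
  }
  rownames(out) <- NULL
  structure(out, n_dropped = n_dropped, protein = protein,
            class = c("pair_observations", "data.frame"))
}

#' Write a results table to CSV or JSON
#'
#' Values round-trip: reading the file back yields the same numbers to at
#' least 12 significant digits (CSV is written with 15).
#'
#' @param rows Data frame of results.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @param allow_empty Permit a zero-row table (header-only file).
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path, format = c("csv", "json"),
                                allow_empty = FALSE) {
  format <- match.arg(format)
  stopifnot(is.data.frame(rows))
  if (nrow(rows) == 0 && !allow_empty) {
    stop("refusing to write an empty results table (set allow_empty = TRUE)")
  }
  if (format == "csv") {
    out <- rows
    for (j in seq_along(out)) {
      if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.15g", out[[j]])
    }
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(rows, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#' @param path File path.
#' @param format `"csv"` or `"json"`.
#' @return A data frame.
#' @export
read_results_table <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    df
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}

#' Write a cohort to the canonical subject-level CSV layout
#' @param cohort A `twin_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  df$zygosity <- as.character(df$zygosity)
  df$sex <- as.character(df$sex)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
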