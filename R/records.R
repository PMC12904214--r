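#' Bin age in years into the model's age categories
#'
#' Ages are discretised into `18-50`, `50-70` and `70+` using right-closed
#' intervals (0, 50], (50, 70], (70, 120].  An age of exactly 50 therefore
#' falls in the first bin and exactly 70 in the second.
#'
#' @param years Numeric vector of ages in years, each in (0, 120].
#' @return Character vector of age bin labels.
#' @examples
#' bin_age(c(50, 51, 70, 70.5))
#' @export
bin_age <- function(years) {
  years <- as.numeric(years)
  bad <- !is.na(years) & (years <= 0 | years > 120)
  if (any(bad))
    stop("age out of range (0, 120]: ", paste(years[bad], collapse = ", "),
         call. = FALSE)
  as.character(cut(years, breaks = c(0, 50, 70, 120),
                   labels = c("18-50", "50-70", "70+"), right = TRUE))
}

#' Bin a Besinger/QMG severity score into the model's categories
#'
#' Scores are discretised into `-1to1`, `1to4`, `4to8` and `8to24` using
#' intervals [-1, 1], (1, 4], (4, 8], (8, 24].
#'
#' @param score Numeric vector of severity scores, each in [-1, 24].
#' @return Character vector of score bin labels.
#' @examples
#' bin_besinger(c(1, 4.5, 24))
#' @export
bin_besinger <- function(score) {
  score <- as.numeric(score)
  bad <- !is.na(score) & (score < -1 | score > 24)
  if (any(bad))
    stop("Besinger/QMG score out of range [-1, 24]: ",
         paste(score[bad], collapse = ", "), call. = FALSE)
  as.character(cut(score, breaks = c(-1, 1, 4, 8, 24),
                   labels = c("-1to1", "1to4", "4to8", "8to24"),
                   right = TRUE, include.lowest = TRUE))
}

# Validate a record data.frame against a network: declared columns only,
# declared states only (NA allowed everywhere). Returns the data.frame with
# columns ordered as in the network.
validate_records <- function(records, network, ignore_unknown = FALSE) {
  stopifnot(is.data.frame(records), inherits(network, "omg_network"))
  nms <- variable_names(network)
  unknown <- setdiff(names(records), nms)
  if (length(unknown)) {
    if (!ignore_unknown)
      stop("unknown column(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    records <- records[setdiff(names(records), unknown)]
  }
  missing_cols <- setdiff(nms, names(records))
  for (m in missing_cols) records[[m]] <- NA_character_
  records <- records[nms]
  for (v in nms) {
    vals <- as.character(records[[v]])
    bad <- !is.na(vals) & !vals %in% network$variables[[v]]$states
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("record ", i, ", column '", v, "': undeclared state '",
           vals[i], "'", call. = FALSE)
    }
    records[[v]] <- vals
  }
  rownames(records) <- NULL
  records
}

#' Read patient records from CSV
#'
#' Reads one record per row with one column per network variable, states as
#' character labels and a configurable missing-value marker.  Raw numeric
#' values in the `age` and `besinger` columns are binned with [bin_age()] and
#' [bin_besinger()] when `bin_raw = TRUE`; already-binned labels pass through.
#'
#' @param path CSV file path.
#' @param network Network whose schema the file must follow
#'   (default [omg_default_network()]).
#' @param missing Missing-value marker in the file (default `"NA"`).
#' @param bin_raw Bin raw numeric age / Besinger values (default `TRUE`).
#' @param ignore_unknown Drop undeclared columns instead of erroring.
#' @return A data.frame of character state labels with `NA` for missing,
#'   columns ordered as in the network.
#' @seealso [write_records()]
#' @export
read_records <- function(path, network = omg_default_network(),
                         missing = "NA", bin_raw = TRUE,
                         ignore_unknown = FALSE) {
  records <- utils::read.csv(path, colClasses = "character",
                             na.strings = missing, check.names = FALSE)
  if (bin_raw) {
    for (v in intersect(c("age", "besinger"), names(records))) {
      vals <- records[[v]]
      numlike <- !is.na(vals) & !is.na(suppressWarnings(as.numeric(vals))) &
        !vals %in% network$variables[[v]]$states
      if (any(numlike)) {
        binner <- if (v == "age") bin_age else bin_besinger
        vals[numlike] <- binner(as.numeric(vals[numlike]))
        records[[v]] <- vals
      }
    }
  }
  validate_records(records, network, ignore_unknown = ignore_unknown)
}

#' Write patient records to CSV
#'
#' Inverse of [read_records()]: `read_records(write_records(x, f))` returns
#' `x` for records already on the binned state labels.
#'
#' @param records Record data.frame (character states, `NA` for missing).
#' @param path Output CSV path.
#' @param missing Marker written for missing values (default `"NA"`).
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, missing = "NA") {
  stopifnot(is.data.frame(records))
  utils::write.csv(records, path, row.names = FALSE, na = missing)
  invisible(path)
}
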