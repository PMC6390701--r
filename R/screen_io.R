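#' Read a long-format interaction screen table
#'
#' Reads the deposited long format of an all-by-all extracellular
#' interaction screen: one row per well, with the bait identifier, the
#' prey identifier, and the raw absorbance at 650 nm. The required
#' column headings are exactly `Bait_ECD`, `Prey_ECD` and `Abs_650_nm`;
#' extra columns are ignored with a warning. Identifiers are trimmed and
#' upper-cased (AGI locus identifiers are case-insensitive in practice).
#'
#' @param path Path to a TSV or CSV file with a header row.
#' @param dialect Field separator convention, `"tsv"` (default) or `"csv"`.
#' @return A data frame with columns `bait`, `prey`, `absorbance`
#'   (one row per well), in file order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("Bait_ECD\tPrey_ECD\tAbs_650_nm",
#'              "AT4G33430\tAT2G23950\t1.23"), tf)
#' read_screen(tf)
#' @export
read_screen <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("screen file not found: ", path, call. = FALSE)
  }
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  required <- c("Bait_ECD", "Prey_ECD", "Abs_650_nm")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(raw), required)
  if (length(extra) > 0L) {
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  bait <- toupper(trimws(raw[["Bait_ECD"]]))
  prey <- toupper(trimws(raw[["Prey_ECD"]]))
  if (any(bait == "") || any(prey == "")) {
    bad <- which(bait == "" | prey == "")[1L]
    stop("empty bait or prey identifier at data line ", bad, call. = FALSE)
  }
  absorbance <- suppressWarnings(as.numeric(raw[["Abs_650_nm"]]))
  bad_num <- which(!is.finite(absorbance))
  if (length(bad_num) > 0L) {
    stop("non-numeric absorbance at data line ", bad_num[1L],
         " (value: '", raw[["Abs_650_nm"]][bad_num[1L]], "')",
         call. = FALSE)
  }
  bad_neg <- which(absorbance < 0)
  if (length(bad_neg) > 0L) {
    stop("negative absorbance at data line ", bad_neg[1L],
         " (value: ", absorbance[bad_neg[1L]], ")", call. = FALSE)
  }
  message("read ", nrow(raw), " interaction record(s) from ", path)
  data.frame(bait = bait, prey = prey, absorbance = absorbance,
             stringsAsFactors = FALSE)
}

#' Write interaction records in the long screen format
#'
#' Inverse of [read_screen()]: writes a `bait`/`prey`/`absorbance` data
#' frame as a TSV with the deposited column headings.
#'
#' @param records Data frame with columns `bait`, `prey`, `absorbance`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_screen <- function(records, path) {
  stopifnot(all(c("bait", "prey", "absorbance") %in% names(records)))
  out <- data.frame(Bait_ECD = records$bait, Prey_ECD = records$prey,
                    Abs_650_nm = format(records$absorbance, digits = 12,
                                        trim = TRUE, scientific = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assemble the orientation-resolved absorbance matrix
#'
#' Pivots long-format well records into a dense bait x prey matrix.
#' Rows are the sorted distinct bait identifiers, columns the sorted
#' distinct prey identifiers. The matrix is not assumed symmetric: cell
#' (i, j) is the measurement with protein i as bait and protein j as
#' prey, and the reciprocal orientation lives at (j, i). Unmeasured
#' cells are `NA`.
#'
#' @param records Data frame with columns `bait`, `prey`, `absorbance`.
#' @param duplicate_policy What to do when an ordered (bait, prey) pair
#'   occurs more than once: `"error"` (default; the screen design has
#'   one well per ordered pair) or `"mean"` (collapse to the mean, with
#'   a message stating how many pairs were collapsed).
#' @return A numeric matrix with bait ids as rownames and prey ids as
#'   colnames.
#' @export
assemble_matrix <- function(records, duplicate_policy = c("error", "mean")) {
  duplicate_policy <- match.arg(duplicate_policy)
  if (nrow(records) == 0L) {
    stop("no records to assemble", call. = FALSE)
  }
  baits <- sort(unique(records$bait))
  preys <- sort(unique(records$prey))
  key <- paste(records$bait, records$prey, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    if (duplicate_policy == "error") {
      pair <- strsplit(dups[1L], "\r", fixed = TRUE)[[1L]]
      stop("duplicate measurement for bait ", pair[1L], " / prey ",
           pair[2L], " (", length(dups),
           " duplicated pair(s); use duplicate_policy = \"mean\" to collapse)",
           call. = FALSE)
    }
    message("collapsing ", length(dups),
            " duplicated (bait, prey) pair(s) by mean")
    agg <- tapply(records$absorbance, key, mean)
    key <- names(agg)
    parts <- strsplit(key, "\r", fixed = TRUE)
    records <- data.frame(bait = vapply(parts, `[`, "", 1L),
                          prey = vapply(parts, `[`, "", 2L),
                          absorbance = as.numeric(agg),
                          stringsAsFactors = FALSE)
  }
  m <- matrix(NA_real_, length(baits), length(preys),
              dimnames = list(baits, preys))
  m[cbind(match(records$bait, baits), match(records$prey, preys))] <-
    records$absorbance
  m
}

#' Write an absorbance or score matrix as TSV
#'
#' First column holds the bait (row) identifiers under the header
#' `Bait_ECD`; remaining column headers are the prey identifiers.
#' Missing cells are written as `NA`. Values keep at least 9
#' significant digits so a write/read round trip is lossless for
#' screen-scale data.
#'
#' @param m Numeric matrix with dimnames (absorbance, residuals or scores).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  txt <- matrix(format(m, digits = 12, trim = TRUE, scientific = FALSE),
                nrow(m), ncol(m))
  txt[is.na(m)] <- "NA"
  out <- cbind(Bait_ECD = rownames(m), txt)
  colnames(out) <- c("Bait_ECD", colnames(m))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix()]
#'
#' @param path TSV path produced by [write_matrix()].
#' @return Numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "")
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- raw[[1L]]
  m
}

#' Export called interactions as an edge list
#'
#' Writes one row per unordered pair in the selected class(es), with the
#' pair identifiers in lexicographic order, both orientation scores, the
#' geometric-mean score, and the class. This flat edge list is the
#' hand-off format for network tools (full PSI-MI formatting is out of
#' scope).
#'
#' @param hits A hit table from [call_hits()].
#' @param path Output file path.
#' @param which Which classes to export: `"bidirectional"`,
#'   `"unidirectional"`, or `"all"` (both hit classes; pairs classed
#'   `none` are never exported).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(hits, path,
                            which = c("all", "bidirectional",
                                      "unidirectional")) {
  which <- match.arg(which)
  keep <- switch(which,
                 all = hits$class %in% c("bidirectional", "unidirectional"),
                 bidirectional = hits$class == "bidirectional",
                 unidirectional = hits$class == "unidirectional")
  sel <- hits[keep, , drop = FALSE]
  out <- data.frame(
    id_a = sel$id_a, id_b = sel$id_b,
    score_bait_prey = format_num(sel$score_ab),
    score_prey_bait = format_num(sel$score_ba),
    geometric_mean_score = format_num(sel$geo_mean),
    class = sel$class, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# fixed-precision numeric formatting with NA token
format_num <- function(x) {
  out <- format(x, digits = 12, trim = TRUE, scientific = FALSE)
  out[is.na(x)] <- "NA"
  out
}
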