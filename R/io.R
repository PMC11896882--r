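# Readers and writers for the census tables (CSV: UTF-8, comma, header,
# "." decimal) with schema validation, plus assembly of site x taxa
# abundance matrices.

fail_rows <- function(what, rows) {
  stop(what, " at row(s) ", paste(utils::head(rows, 10), collapse = ", "),
       if (length(rows) > 10) sprintf(" (+%d more)", length(rows) - 10),
       call. = FALSE)
}

need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
}

#' Validate a tree stem table
#'
#' Checks DBH >= 10 cm where present, wood density in (0.05, 1.5), and
#' (when `plot_side` is given) coordinates within plot bounds. Violations
#' are reported with row numbers.
#'
#' @param trees data.frame to validate.
#' @param plot_side optional plot edge (m) for the coordinate check.
#' @return `trees`, invisibly, if valid.
#' @export
validate_stem_table <- function(trees, plot_side = NULL) {
  need_cols(trees, c("stem_id", "plot_id", "species", "x", "y",
                     "dbh_census1", "dbh_census2", "wood_density"),
            "stem table")
  for (cn in c("dbh_census1", "dbh_census2")) {
    bad <- which(!is.na(trees[[cn]]) & trees[[cn]] < 10)
    if (length(bad)) fail_rows(paste0(cn, " < 10 cm"), bad)
  }
  bad <- which(is.na(trees$dbh_census1) & is.na(trees$dbh_census2))
  if (length(bad)) fail_rows("stem absent from both censuses", bad)
  bad <- which(!(trees$wood_density > 0.05 & trees$wood_density < 1.5))
  if (length(bad)) fail_rows("wood_density outside (0.05, 1.5)", bad)
  if (!is.null(plot_side)) {
    bad <- which(trees$x < 0 | trees$x > plot_side |
                   trees$y < 0 | trees$y > plot_side)
    if (length(bad)) fail_rows("coordinates outside plot bounds", bad)
  }
  invisible(trees)
}

#' Validate a liana table
#'
#' Checks diameters >= 1 cm, mechanism labels, and (when `trees` is given)
#' that host stem ids resolve to stem-table rows.
#'
#' @param lianas data.frame to validate.
#' @param trees optional stem table for host id resolution.
#' @return `lianas`, invisibly, if valid.
#' @export
validate_liana_table <- function(lianas, trees = NULL) {
  need_cols(lianas, c("liana_id", "taxon", "quadrat_id", "diameter",
                      "host1_stem_id", "host2_stem_id", "mechanism"),
            "liana table")
  bad <- which(!(lianas$diameter >= 1))
  if (length(bad)) fail_rows("diameter < 1 cm", bad)
  bad <- which(!lianas$mechanism %in% c("active", "passive", "unknown"))
  if (length(bad)) fail_rows("unknown climbing mechanism", bad)
  if (!is.null(trees)) {
    for (cn in c("host1_stem_id", "host2_stem_id")) {
      h <- lianas[[cn]]
      bad <- which(!is.na(h) & !(h %in% trees$stem_id))
      if (length(bad)) fail_rows(paste(cn, "does not resolve"), bad)
    }
  }
  invisible(lianas)
}

#' Validate a taxon trait table
#' @param traits data.frame with `taxon` plus trait columns.
#' @return `traits`, invisibly, if valid.
#' @export
validate_trait_table <- function(traits) {
  need_cols(traits, "taxon", "trait table")
  dup <- which(duplicated(traits$taxon))
  if (length(dup)) fail_rows("duplicated taxon", dup)
  num <- setdiff(names(traits), "taxon")
  for (cn in num) {
    bad <- which(!is.finite(traits[[cn]]) | traits[[cn]] <= 0)
    if (length(bad)) fail_rows(paste(cn, "not finite and positive"), bad)
  }
  invisible(traits)
}

#' Write / read census tables
#'
#' Thin CSV wrappers that validate on both ends so every file a writer
#' emits is accepted by its reader.
#'
#' @param x table to write.
#' @param path file path.
#' @param ... passed to the matching validator (e.g. `trees` for
#'   [validate_liana_table]).
#' @return the table (readers) or `path` invisibly (writers).
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_stem_table <- function(x, path, ...) {
  validate_stem_table(x, ...)
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname table_io
#' @export
read_stem_table <- function(path, ...) {
  x <- utils::read.csv(path, fileEncoding = "UTF-8")
  validate_stem_table(x, ...)
  x
}

#' @rdname table_io
#' @export
write_liana_table <- function(x, path, ...) {
  validate_liana_table(x, ...)
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname table_io
#' @export
read_liana_table <- function(path, ...) {
  x <- utils::read.csv(path, fileEncoding = "UTF-8")
  x$host1_stem_id <- as.character(x$host1_stem_id)
  x$host2_stem_id <- as.character(x$host2_stem_id)
  validate_liana_table(x, ...)
  x
}

#' @rdname table_io
#' @export
write_trait_table <- function(x, path) {
  validate_trait_table(x)
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname table_io
#' @export
read_trait_table <- function(path) {
  validate_trait_table(utils::read.csv(path, fileEncoding = "UTF-8"))
}

#' Build a site x taxa abundance matrix
#'
#' Counts stems per quadrat and taxon. Lianas are counted at the quadrat
#' level through their `quadrat_id`; trees at the buffered-window level
#' through their coordinates (half-open window membership), restricted to
#' stems alive in the chosen census.
#'
#' @param x a liana or stem table.
#' @param frame a [quadrat_frame].
#' @param level `"quadrat"` (uses `quadrat_id`) or `"buffered"` (uses
#'   coordinates against the buffered window bounds).
#' @param census census used to filter tree stems at the buffered level.
#' @return integer matrix, rows = quadrat ids, columns = taxa.
#' @export
build_abundance_matrix <- function(x, frame, level = c("quadrat", "buffered"),
                                   census = 2) {
  level <- match.arg(level)
  if (level == "quadrat") {
    bad <- setdiff(unique(x$quadrat_id), frame$quadrat_id)
    if (length(bad)) stop("unknown quadrat id(s): ", paste(bad, collapse = ", "))
    tab <- table(factor(x$quadrat_id, levels = frame$quadrat_id),
                 factor(x$taxon))
  } else {
    dcol <- if (census == 2) "dbh_census2" else "dbh_census1"
    x <- x[!is.na(x[[dcol]]), , drop = FALSE]
    taxa <- sort(unique(x$species))
    tab <- matrix(0L, nrow(frame), length(taxa),
                  dimnames = list(frame$quadrat_id, taxa))
    # windows may overlap in principle, so count per window
    for (i in seq_len(nrow(frame))) {
      inw <- x$plot_id == frame$plot_id[i] &
        x$x >= frame$bxmin[i] & x$x < frame$bxmax[i] &
        x$y >= frame$bymin[i] & x$y < frame$bymax[i]
      if (any(inw))
        tab[i, ] <- tab[i, ] + as.integer(table(factor(x$species[inw],
                                                       levels = taxa)))
    }
  }
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  m
}

#' Drop rare taxa from an abundance matrix
#'
#' @param A abundance matrix (sites x taxa).
#' @param min_total minimum column total a taxon must reach to be kept.
#' @return the column-subset matrix.
#' @export
subset_min_abundance <- function(A, min_total) {
  A[, colSums(A) >= min_total, drop = FALSE]
}
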