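#' Construct a genetic map
#'
#' A genetic map is an ordered set of molecular markers with centiMorgan
#' positions along named chromosomes. The object is a plain `data.frame`
#' with columns `chromosome`, `marker`, `position_cM` and `marker_type`,
#' carrying the map identifier as an attribute and kept sorted within each
#' chromosome by `(position_cM, marker)` so that marker order is
#' reproducible even under position ties.
#'
#' @param markers data.frame with columns `chromosome`, `marker`,
#'   `position_cM` and optionally `marker_type` (defaults to `"SNP"`).
#' @param map_id single string identifying the map.
#' @return An object of class `genetic_map` (a sorted data.frame).
#' @examples
#' m <- genetic_map(data.frame(
#'   chromosome = "1A", marker = c("m1", "m2"),
#'   position_cM = c(0, 12.5), marker_type = "SSR"), "demo")
#' map_id(m)
#' @export
genetic_map <- function(markers, map_id) {
  stopifnot(is.character(map_id) || is.factor(map_id), length(map_id) == 1L)
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  required <- c("chromosome", "marker", "position_cM")
  missing_cols <- setdiff(required, names(markers))
  if (length(missing_cols)) {
    stop("genetic map is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(markers$marker_type)) {
    markers$marker_type <- rep("SNP", nrow(markers))
  }
  markers$chromosome <- as.character(markers$chromosome)
  markers$marker <- as.character(markers$marker)
  markers$marker_type <- as.character(markers$marker_type)
  markers$position_cM <- as.numeric(markers$position_cM)
  markers <- markers[, c("chromosome", "marker", "position_cM", "marker_type")]

  if (nrow(markers)) {
    if (anyNA(markers$position_cM)) {
      stop("non-numeric marker position in map '", map_id, "' (row ",
           which(is.na(markers$position_cM))[1L], ")")
    }
    if (any(markers$position_cM < 0)) {
      stop("negative marker position in map '", map_id, "' (row ",
           which(markers$position_cM < 0)[1L], ")")
    }
    if (anyDuplicated(markers$marker)) {
      dup <- markers$marker[duplicated(markers$marker)][1L]
      stop("duplicated marker name '", dup, "' in map '", map_id, "'")
    }
    if (any(!nzchar(markers$chromosome))) {
      stop("empty chromosome label in map '", map_id, "'")
    }
    markers <- markers[order(markers$chromosome, markers$position_cM,
                             markers$marker, method = "radix"), , drop = FALSE]
    rownames(markers) <- NULL
  }
  structure(markers, map_id = map_id, class = c("genetic_map", "data.frame"))
}

#' @rdname genetic_map
#' @param x a `genetic_map`.
#' @export
map_id <- function(x) attr(x, "map_id")

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("Genetic map '%s': %d markers on %d chromosome(s)\n",
              map_id(x), nrow(x), length(unique(x$chromosome))))
  NextMethod()
}

#' Read a genetic map from a tab-separated file
#'
#' Expects a header line `chromosome<TAB>marker<TAB>position_cM<TAB>marker_type`
#' and one marker per row. Positions must be non-negative numbers; duplicate
#' marker names within the file are rejected.
#'
#' @param path path to the file.
#' @param map_id map identifier assigned to the result; defaults to the
#'   file name without extension.
#' @return A [genetic_map()].
#' @export
read_map <- function(path, map_id = sub("\\.[^.]*$", "", basename(path))) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  required <- c("chromosome", "marker", "position_cM", "marker_type")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("map file '", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  pos <- suppressWarnings(as.numeric(tab$position_cM))
  bad <- which(is.na(pos) | pos < 0)
  if (length(bad)) {
    stop("invalid position '", tab$position_cM[bad[1L]], "' in '", path,
         "' at line ", bad[1L] + 1L)  # +1 for the header line
  }
  tab$position_cM <- pos
  genetic_map(tab, map_id)
}

#' Write a genetic map to a tab-separated file
#'
#' Positions are printed with two decimals; the column layout matches
#' [read_map()].
#'
#' @param map a `genetic_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  out <- as.data.frame(map)
  out$position_cM <- sprintf("%.2f", round_half_up(out$position_cM, 2))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Round half away from zero (base round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
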