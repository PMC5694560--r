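#' Merge genetic maps into a consensus map
#'
#' The first map (by default the densest, mirroring the use of the densest
#' public map as backbone) provides the consensus coordinate system. Each
#' subsequent map is first screened against the running consensus with
#' [check_order_consistency()]; conflicted markers are dropped from the
#' incoming map only. The retained shared markers of each chromosome form
#' the anchor frame through which the incoming map's unique markers are
#' projected ([project_position()]). Shared markers keep their consensus
#' position. Chromosomes sharing fewer than two consistent markers with
#' the consensus contribute no projected markers.
#'
#' @param maps list of `genetic_map` objects.
#' @param order `"given"` to merge in list order, `"by_size"` (default) to
#'   merge in descending marker count.
#' @param map_id identifier for the consensus map.
#' @return A `genetic_map` with attributes `conflicts` (all conflict rows
#'   accumulated across merges) and `merge_log` (data.frame with one row
#'   per merged map: markers in, shared, conflicted, projected, skipped).
#' @export
merge_maps <- function(maps, order = c("by_size", "given"),
                       map_id = "consensus") {
  order <- match.arg(order)
  if (!length(maps)) stop("merge_maps() needs at least one map")
  stopifnot(all(vapply(maps, inherits, logical(1L), "genetic_map")))
  if (order == "by_size") {
    maps <- maps[base::order(-vapply(maps, nrow, integer(1L)))]
  }

  consensus <- genetic_map(as.data.frame(maps[[1L]]), map_id)
  conflicts <- NULL
  log_rows <- list(data.frame(
    map = map_id(maps[[1L]]), n_markers = nrow(maps[[1L]]),
    n_shared = nrow(maps[[1L]]), n_conflicted = 0L,
    n_projected = 0L, n_skipped = 0L, stringsAsFactors = FALSE))

  for (m in maps[-1L]) {
    report <- check_order_consistency(consensus, m)
    conflicted <- unique(report$conflicts$marker)
    incoming <- as.data.frame(m)
    incoming <- incoming[!(incoming$marker %in% conflicted), , drop = FALSE]
    # unique markers = not already named in the consensus
    uniq <- incoming[!(incoming$marker %in% consensus$marker), , drop = FALSE]

    projected <- list()
    skipped <- 0L
    for (chr in unique(uniq$chromosome)) {
      anchors <- report$retained[report$retained$chromosome == chr, , drop = FALSE]
      rows <- uniq[uniq$chromosome == chr, , drop = FALSE]
      frame <- anchor_frame(anchors$position_b, anchors$position_a)
      if (n_anchors(frame) < 2L) {
        warning("map '", map_id(m), "', chromosome ", chr, ": fewer than 2 ",
                "consistent shared markers; ", nrow(rows),
                " marker(s) not projected", call. = FALSE)
        skipped <- skipped + nrow(rows)
        next
      }
      rows$position_cM <- pmax(0, project_position(rows$position_cM, frame))
      projected[[chr]] <- rows
    }
    n_proj <- 0L
    if (length(projected)) {
      add <- do.call(rbind, projected)
      n_proj <- nrow(add)
      consensus <- genetic_map(rbind(as.data.frame(consensus), add), map_id)
    }
    conflicts <- rbind(conflicts, report$conflicts)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      map = map_id(m), n_markers = nrow(m),
      n_shared = nrow(report$retained), n_conflicted = length(conflicted),
      n_projected = n_proj, n_skipped = skipped, stringsAsFactors = FALSE)
  }
  if (is.null(conflicts)) {
    conflicts <- data.frame(
      marker = character(), map_a = character(), map_b = character(),
      chromosome_a = character(), chromosome_b = character(),
      reason = character(), stringsAsFactors = FALSE)
  }
  attr(consensus, "conflicts") <- conflicts
  attr(consensus, "merge_log") <- do.call(rbind, log_rows)
  consensus
}
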