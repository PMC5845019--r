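#' Construct a rectangular source/detector probe grid
#'
#' Builds an optode grid with the given number of rows and columns at a fixed
#' inter-optode pitch, alternating sources and detectors in a checkerboard
#' pattern, and enumerates all measurement channels, i.e. all source-detector
#' pairs whose separation equals the pitch (nearest neighbours).
#'
#' Channel numbering is row-major from the top row of the probe downward:
#' channel midpoints are sorted by vertical position first, then left to
#' right.  For the default 4x5 grid this interleaves rows of horizontal
#' pairs (4 channels) with rows of vertical pairs (5 channels), giving the
#' sequence 4,5,4,5,4,5,4 = 31 channels.  Low channel ids therefore sit over
#' frontal cortex and high ids over posterior cortex.
#'
#' @param n_rows,n_cols grid dimensions in optodes.
#' @param pitch_cm inter-optode distance in cm (default 3).
#' @return an object of class `probe_layout`: a list with elements
#'   `optodes` (data.frame: id, role, x_cm, y_cm), `channels` (data.frame:
#'   id, source_id, detector_id, x_cm, y_cm, hemisphere, roi),
#'   `grid_shape` (rows, cols) and `pitch_cm`.
#' @seealso [build_default_layout()], [assign_rois()]
#' @export
build_layout <- function(n_rows, n_cols, pitch_cm = 3) {
  if (n_rows < 1 || n_cols < 1)
    stop("grid must have at least one row and one column")
  grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  optodes <- data.frame(
    id = seq_len(nrow(grid)),
    role = ifelse((grid$row + grid$col) %% 2 == 0, "source", "detector"),
    x_cm = (grid$col - 1) * pitch_cm,
    y_cm = (grid$row - 1) * pitch_cm,
    stringsAsFactors = FALSE
  )
  # all source-detector pairs at separation exactly = pitch
  src <- optodes[optodes$role == "source", , drop = FALSE]
  det <- optodes[optodes$role == "detector", , drop = FALSE]
  pairs <- expand.grid(s = src$id, d = det$id)
  sx <- optodes$x_cm[pairs$s]; sy <- optodes$y_cm[pairs$s]
  dx <- optodes$x_cm[pairs$d]; dy <- optodes$y_cm[pairs$d]
  sep <- sqrt((sx - dx)^2 + (sy - dy)^2)
  keep <- abs(sep - pitch_cm) < 1e-9
  ch <- data.frame(
    source_id = pairs$s[keep], detector_id = pairs$d[keep],
    x_cm = (sx + dx)[keep] / 2, y_cm = (sy + dy)[keep] / 2
  )
  ord <- order(ch$y_cm, ch$x_cm)
  ch <- ch[ord, , drop = FALSE]
  ch <- data.frame(id = seq_len(nrow(ch)), ch, row.names = NULL)
  layout <- structure(
    list(optodes = optodes, channels = ch,
         grid_shape = c(rows = n_rows, cols = n_cols), pitch_cm = pitch_cm),
    class = "probe_layout"
  )
  layout$channels$hemisphere <- .hemisphere_labels(layout)
  layout$channels$roi <- "none"
  layout
}

#' Canonical 31-channel probe layout
#'
#' The default geometry: 20 optodes (10 sources, 10 detectors) in a 4x5
#' checkerboard grid spanning 9 cm x 12 cm at 3 cm pitch, yielding 31
#' nearest-neighbour channels (16 horizontal + 15 vertical pairs).  ROI
#' labels (PFC, pre-motor/SMA, M1, SMC) are attached via [assign_rois()].
#'
#' @return a `probe_layout` with 31 channels and ROI labels assigned.
#' @examples
#' layout <- build_default_layout()
#' nrow(layout$channels)  # 31
#' @export
build_default_layout <- function() {
  assign_rois(build_layout(4, 5, pitch_cm = 3))
}

# canonical ROI channel lists for the 31-channel layout
.roi_table <- function() {
  list(
    "PFC.left"    = c(1, 2, 5, 6),
    "PFC.right"   = c(3, 4, 7, 8),
    "preSMA.left" = c(10, 11, 15),
    "preSMA.right"= c(12, 13, 17),
    "M1.left"     = c(14, 19, 20),
    "M1.right"    = c(18, 21, 22),
    "SMC.left"    = c(23, 24, 28, 29),
    "SMC.right"   = c(26, 27, 30, 31)
  )
}

#' Attach region-of-interest labels to the canonical layout
#'
#' ROIs are fixed channel groupings: prefrontal cortex (PFC) channels
#' 1,2,5,6 (left) and 3,4,7,8 (right); pre-motor/supplementary motor area
#' (preSMA) 10,11,15 (left) and 12,13,17 (right); primary motor cortex (M1)
#' 14,19,20 (left) and 18,21,22 (right); somatosensory motor cortex (SMC)
#' 23,24,28,29 (left) and 26,27,30,31 (right).  Channels 9, 16 and 25
#' belong to no ROI.
#'
#' @param layout a `probe_layout` with exactly 31 channels.
#' @return the layout with `roi` and (where the ROI lists imply a side)
#'   `hemisphere` columns filled in.
#' @export
assign_rois <- function(layout) {
  stopifnot(inherits(layout, "probe_layout"))
  if (nrow(layout$channels) != 31L)
    stop("ROI labels are defined for the canonical 31-channel layout; got ",
         nrow(layout$channels), " channels")
  rois <- .roi_table()
  layout$channels$roi <- "none"
  for (nm in names(rois)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    ids <- rois[[nm]]
    layout$channels$roi[ids] <- parts[1]
    # the ROI lists state each listed channel's side; they override the
    # geometric rule for midline channels (e.g. channel 7)
    layout$channels$hemisphere[ids] <- parts[2]
  }
  layout
}

# geometric hemisphere rule: midline = centre of the grid's x extent;
# strictly left of it -> left, strictly right -> right, on it -> left
.hemisphere_labels <- function(layout) {
  x <- layout$channels$x_cm
  mid <- (min(layout$optodes$x_cm) + max(layout$optodes$x_cm)) / 2
  ifelse(x > mid + 1e-9, "right", "left")
}

#' Channel ids on one hemisphere
#'
#' Partitions the channels by the x coordinate of their midpoints relative
#' to the grid midline.  Channels exactly on the midline default to the left
#' hemisphere unless an ROI list assigns them otherwise (see
#' [assign_rois()]); every channel belongs to exactly one side.
#'
#' @param layout a `probe_layout`.
#' @param side `"left"` or `"right"`.
#' @return integer vector of channel ids.
#' @export
hemisphere_channels <- function(layout, side = c("left", "right")) {
  side <- match.arg(side)
  layout$channels$id[layout$channels$hemisphere == side]
}

#' Channel ids of one ROI (optionally one side)
#'
#' @param layout a `probe_layout` with ROIs assigned.
#' @param roi one of `"PFC"`, `"preSMA"`, `"M1"`, `"SMC"`.
#' @param side optional `"left"` or `"right"`.
#' @return integer vector of channel ids.
#' @export
roi_channels <- function(layout, roi, side = NULL) {
  ch <- layout$channels
  keep <- ch$roi == roi
  if (!is.null(side)) keep <- keep & ch$hemisphere == side
  ids <- ch$id[keep]
  if (length(ids) == 0) stop("no channels in ROI ", roi)
  ids
}

#' Write / read a probe layout as tab-separated text
#'
#' One row per channel (id, source, detector, midpoint coordinates,
#' hemisphere, ROI); round-trips exactly.
#'
#' @param layout a `probe_layout`.
#' @param path file path.
#' @return `read_layout` returns a `probe_layout` (channel table only;
#'   optode table is reconstructed from the grid shape header).
#' @export
write_layout <- function(layout, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# grid_rows: %d", layout$grid_shape[["rows"]]), con)
  writeLines(sprintf("# grid_cols: %d", layout$grid_shape[["cols"]]), con)
  writeLines(sprintf("# pitch_cm: %.17g", layout$pitch_cm), con)
  utils::write.table(layout$channels, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  hdr <- readLines(path, n = 3)
  val <- function(i) sub("^# [a-z_]+: ", "", hdr[i])
  lay <- build_layout(as.integer(val(1)), as.integer(val(2)),
                      pitch_cm = as.numeric(val(3)))
  ch <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!identical(ch$id, lay$channels$id))
    stop("layout file channel ids do not match the declared grid")
  lay$channels <- ch
  lay
}
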