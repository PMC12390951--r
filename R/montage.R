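# Optode montage ---------------------------------------------------------
#
# A bilateral high-density patch: per hemisphere, 10 emitters and 8
# detectors on a staggered 2-D scalp grid (emitter and detector columns
# alternate; 18 mm column pitch, 17 mm row pitch). Every emitter-detector
# pair with separation in [15, 40] mm is a candidate channel; the right
# hemisphere keeps the 40 shortest-separation pairs and the left keeps 39,
# matching the channel counts of the reference montage. Channel position is the
# emitter-detector midpoint (the maximum-depth point of the banana-shaped
# sensitivity profile). Analysis regions (auditory, sensorimotor,
# premotor) are declared per channel from the midpoint coordinates and are
# mirrored across hemispheres.

#' Build the default bilateral montage
#'
#' @param n_left,n_right Channels retained per hemisphere (defaults 39/40).
#' @return An `fnirs_montage`: list with `optodes` (data frame: hemisphere,
#'   role, index, x_mm, y_mm) and `channels` (data frame: channel, hemisphere,
#'   emitter, detector, separation_mm, mid_x_mm, mid_y_mm, roi).
#' @export
build_montage <- function(n_left = 39L, n_right = 40L) {
  optodes_hemi <- function() {
    g <- expand.grid(col = 1:6, row = 1:3)
    g$x <- (g$col - 1) * 18
    g$y <- (g$row - 1) * 17
    g$role <- ifelse(g$col %% 2 == 1, "emitter", "detector")
    # 9 + 9 -> 10 emitters / 8 detectors: corner detector becomes emitter
    g$role[g$col == 6 & g$row == 3] <- "emitter"
    g
  }
  channels_hemi <- function(opt, n_keep, hemi, sign_x) {
    em <- opt[opt$role == "emitter", ]
    de <- opt[opt$role == "detector", ]
    pairs <- expand.grid(e = seq_len(nrow(em)), d = seq_len(nrow(de)))
    sep <- sqrt((em$x[pairs$e] - de$x[pairs$d])^2 +
                (em$y[pairs$e] - de$y[pairs$d])^2)
    ok <- sep >= 15 & sep <= 40
    pairs <- pairs[ok, ]
    sep <- sep[ok]
    ord <- order(sep, pairs$e, pairs$d)
    pairs <- pairs[ord, ][seq_len(n_keep), ]
    sep <- sep[ord][seq_len(n_keep)]
    mx <- (em$x[pairs$e] + de$x[pairs$d]) / 2
    my <- (em$y[pairs$e] + de$y[pairs$d]) / 2
    data.frame(hemisphere = hemi,
               emitter = pairs$e, detector = pairs$d,
               separation_mm = sep,
               mid_x_mm = sign_x * mx, mid_y_mm = my,
               roi = assign_roi(mx, my))
  }
  opt <- optodes_hemi()
  right <- channels_hemi(opt, n_right, "right", +1)
  left <- channels_hemi(opt, n_left, "left", -1)
  channels <- rbind(left, right)
  channels$channel <- seq_len(nrow(channels))
  channels <- channels[, c("channel", "hemisphere", "emitter", "detector",
                           "separation_mm", "mid_x_mm", "mid_y_mm", "roi")]
  optodes <- rbind(cbind(opt[, c("role", "x", "y")], hemisphere = "right"),
                   cbind(transform(opt[, c("role", "x", "y")], x = -x),
                         hemisphere = "left"))
  names(optodes)[2:3] <- c("x_mm", "y_mm")
  structure(list(optodes = optodes, channels = channels),
            class = "fnirs_montage")
}

# ROI bands in hemisphere-local coordinates (x grows away from the front).
# The patch covers temporal cortex plus parts of frontal, premotor,
# sensorimotor and parietal regions; the three analysis ROIs each contain
# at least 3 channels per hemisphere.
assign_roi <- function(x, y) {
  roi <- rep("temporal", length(x))
  roi[y <= 10 & x >= 20 & x <= 70] <- "auditory"
  roi[y > 10 & x >= 25 & x < 45] <- "premotor"
  roi[y > 10 & x >= 45 & x < 68] <- "sensorimotor"
  roi[y > 10 & x < 25] <- "frontal"
  roi[y > 10 & x >= 68] <- "parietal"
  roi
}

#' Channel indices belonging to a ROI/hemisphere
#' @param montage An `fnirs_montage`.
#' @param roi ROI label (or vector of labels).
#' @param hemisphere "left", "right" or both (default).
#' @return Integer channel ids.
#' @export
roi_channels <- function(montage, roi, hemisphere = c("left", "right")) {
  ch <- montage$channels
  ch$channel[ch$roi %in% roi & ch$hemisphere %in% hemisphere]
}

#' Channel neighbour matrix from midpoint distances
#'
#' Two channels are neighbours when their midpoints lie within
#' `radius_mm`. Hemispheres never bridge (midpoints are mirrored across
#' x = 0 and far apart).
#'
#' @param montage An `fnirs_montage`.
#' @param radius_mm Neighbourhood radius; default [default_neighbor_radius()].
#' @return Logical adjacency matrix (diagonal FALSE).
#' @export
neighbor_matrix <- function(montage, radius_mm = NULL) {
  if (is.null(radius_mm)) radius_mm <- default_neighbor_radius(montage)
  ch <- montage$channels
  d <- as.matrix(stats::dist(cbind(ch$mid_x_mm, ch$mid_y_mm)))
  adj <- d <= radius_mm & d > 0
  dimnames(adj) <- list(ch$channel, ch$channel)
  adj
}

#' Smallest radius giving every channel at least `min_neighbors` neighbours
#' @param montage An `fnirs_montage`.
#' @param min_neighbors Default 2.
#' @return Radius in mm.
#' @export
default_neighbor_radius <- function(montage, min_neighbors = 2L) {
  ch <- montage$channels
  d <- as.matrix(stats::dist(cbind(ch$mid_x_mm, ch$mid_y_mm)))
  diag(d) <- Inf
  # per channel, distance to its min_neighbors-th nearest neighbour
  kth <- apply(d, 1, function(r) sort(r)[min_neighbors])
  max(kth)
}
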