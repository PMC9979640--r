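# Cell tracking across consecutive frames: greedy mutual-nearest-neighbor
# matching with a maximum-displacement gate. Unmatched cells start or end
# tracks; the temporal-smoothness penalty applies only within tracks.

#' Track cells across consecutive frames
#'
#' Greedy mutual-nearest-neighbor matching: in each consecutive frame
#' pair, a cell in frame t and a cell in frame t+1 are linked when each is
#' the other's nearest neighbor and the displacement does not exceed
#' `max_displacement_um`; linked pairs are removed and matching repeats
#' until no mutual pair remains within the gate.
#'
#' @param cells Long data frame of cell positions with columns
#'   `frame_index`, `cell_id`, `x_um`, `y_um`.
#' @param max_displacement_um Gate (um per frame interval). Default 30.
#' @return Data frame with columns `frame_from`, `id_from`, `id_to`
#'   (class `cell_tracking`); zero rows for single-frame input.
#' @export
track_cells <- function(cells, max_displacement_um = 30) {
  stopifnot(is.data.frame(cells),
            all(c("frame_index", "cell_id", "x_um", "y_um") %in% names(cells)))
  frames <- sort(unique(cells$frame_index))
  out <- list()
  if (length(frames) >= 2) {
    for (k in seq_len(length(frames) - 1)) {
      a <- cells[cells$frame_index == frames[k], ]
      b <- cells[cells$frame_index == frames[k + 1], ]
      if (nrow(a) == 0L || nrow(b) == 0L) next
      d <- sqrt(outer(a$x_um, b$x_um, "-")^2 + outer(a$y_um, b$y_um, "-")^2)
      rownames(d) <- a$cell_id
      colnames(d) <- b$cell_id
      avail_r <- rep(TRUE, nrow(d))
      avail_c <- rep(TRUE, ncol(d))
      repeat {
        sub <- d
        sub[!avail_r, ] <- Inf
        sub[, !avail_c] <- Inf
        if (all(!is.finite(sub)) || min(sub) > max_displacement_um) break
        ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
        i <- ij[1]; j <- ij[2]
        # mutual nearest among available by construction of the global min
        out[[length(out) + 1L]] <- data.frame(
          frame_from = frames[k],
          id_from = rownames(d)[i], id_to = colnames(d)[j])
        avail_r[i] <- FALSE
        avail_c[j] <- FALSE
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(frame_from = integer(), id_from = character(), id_to = character())
  rownames(res) <- NULL
  class(res) <- c("cell_tracking", "data.frame")
  res
}
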