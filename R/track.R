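#' Link per-frame labels into identity-stable tracks
#'
#' Frame-to-frame assignment on weighted centroid distances, solved per frame
#' pair as an optimal bipartite matching (maximum-weight matching with weight
#' `K - distance`, which maximises the number of links first and minimises
#' total distance among maximal matchings). Tracks missing for up to
#' `max_gap` frames stay open with a proportionally widened gate. An
#' unmatched detection adjacent to a track whose successor was already
#' claimed is interpreted as a division: the parent track is closed and two
#' daughter tracks open with recorded lineage.
#'
#' @param seg output of [segment_movie()].
#' @param max_link_distance maximum centroid displacement per frame step, um.
#'   The default 15 um corresponds to ~5x the displacement expected from
#'   paper-scale speeds (~35 um/h) at 5-minute sampling.
#' @param max_gap tolerated disappearance, frames.
#' @return `seg` augmented with a `track_id` column in `table` and a
#'   `lineage` data.frame (`track_id`, `parent`, `start_frame`, `end_frame`).
#' @export
link_tracks <- function(seg, max_link_distance = 15, max_gap = 2) {
  tab <- seg$table
  n_fr <- length(seg$labels)
  if (!is.null(tab) && nrow(tab) && max(tab$frame) > n_fr) {
    stop("link_tracks: object table references frames beyond the label movie")
  }
  if (is.null(tab) || nrow(tab) == 0) {
    seg$table <- cbind(tab, track_id = integer(0))
    seg$lineage <- data.frame(track_id = integer(), parent = integer(),
                              start_frame = integer(), end_frame = integer())
    return(seg)
  }
  tab$track_id <- NA_integer_

  # open-track registry
  tr_id <- integer(0); tr_last_frame <- integer(0)
  tr_pos <- matrix(numeric(0), 0, 2)
  parent_of <- integer(0); start_of <- integer(0); end_of <- integer(0)
  new_track <- function(parent = NA_integer_, frame) {
    id <- length(parent_of) + 1L
    parent_of[id] <<- parent; start_of[id] <<- frame; end_of[id] <<- frame
    id
  }

  first_f <- min(tab$frame)
  rows1 <- which(tab$frame == first_f)
  for (r in rows1) {
    id <- new_track(frame = first_f)
    tab$track_id[r] <- id
    tr_id <- c(tr_id, id); tr_last_frame <- c(tr_last_frame, first_f)
    tr_pos <- rbind(tr_pos, c(tab$x_um[r], tab$y_um[r]))
  }

  for (f in setdiff(sort(unique(tab$frame)), first_f)) {
    rows <- which(tab$frame == f)
    det <- cbind(tab$x_um[rows], tab$y_um[rows])
    open <- which(tr_last_frame >= f - 1L - max_gap)
    assigned <- rep(NA_integer_, length(rows))   # index into `open`
    if (length(open) && length(rows)) {
      gap <- f - tr_last_frame[open]             # >= 1
      D <- outer(seq_along(open), seq_len(nrow(det)),
                 Vectorize(function(i, j) sqrt(sum((tr_pos[open[i], ] - det[j, ])^2))))
      gate <- max_link_distance * gap
      allowed <- which(D <= gate, arr.ind = TRUE)
      if (nrow(allowed)) {
        assigned <- .assign_bipartite(D, allowed, length(open), nrow(det))
      }
    }
    matched_tracks <- assigned[!is.na(assigned)]
    for (j in seq_along(rows)) {
      if (!is.na(assigned[j])) {
        oi <- open[assigned[j]]
        id <- tr_id[oi]
        tab$track_id[rows[j]] <- id
        tr_last_frame[oi] <- f; tr_pos[oi, ] <- det[j, ]
        end_of[id] <- f
      }
    }
    # unmatched detections: division if next to a track already claimed this frame
    for (j in seq_along(rows)) {
      if (!is.na(assigned[j])) next
      div_parent <- NA_integer_; div_sib_row <- NA_integer_
      if (length(open)) {
        cand <- open[tr_last_frame[open] == f]  # tracks matched this frame
        if (length(cand)) {
          # parent position = its position at the previous frame: approximate
          # by current sibling detection distance
          dd <- sqrt(rowSums((tr_pos[cand, , drop = FALSE] -
                              matrix(det[j, ], length(cand), 2, byrow = TRUE))^2))
          k <- which.min(dd)
          if (dd[k] <= 2 * max_link_distance) {
            div_parent <- tr_id[cand[k]]
          }
        }
      }
      if (!is.na(div_parent)) {
        # close the parent at f-1; re-home its detection this frame and the
        # current one as daughters
        sib_row <- rows[which(tab$track_id[rows] == div_parent)]
        end_of[div_parent] <- f - 1L
        d1 <- new_track(parent = div_parent, frame = f)
        d2 <- new_track(parent = div_parent, frame = f)
        if (length(sib_row) == 1) {
          tab$track_id[sib_row] <- d1
          oi <- which(tr_id == div_parent)
          tr_id[oi] <- d1   # registry slot now carries daughter 1
        }
        tab$track_id[rows[j]] <- d2
        tr_id <- c(tr_id, d2); tr_last_frame <- c(tr_last_frame, f)
        tr_pos <- rbind(tr_pos, det[j, ])
        end_of[d1] <- f; end_of[d2] <- f
      } else {
        id <- new_track(frame = f)
        tab$track_id[rows[j]] <- id
        tr_id <- c(tr_id, id); tr_last_frame <- c(tr_last_frame, f)
        tr_pos <- rbind(tr_pos, det[j, ])
      }
    }
  }
  seg$table <- tab
  seg$lineage <- data.frame(track_id = seq_along(parent_of), parent = parent_of,
                            start_frame = start_of, end_frame = end_of)
  seg
}

# optimal bipartite assignment over the allowed (gated) edges:
# maximum-weight matching with weights K - d, K large enough that match
# count dominates total distance
.assign_bipartite <- function(D, allowed, n_a, n_b) {
  K <- max(D[allowed]) * (n_a + n_b + 1) + 1
  edges <- data.frame(from = paste0("a", allowed[, 1]),
                      to = paste0("b", allowed[, 2]),
                      weight = K - D[allowed])
  verts <- data.frame(name = c(paste0("a", seq_len(n_a)), paste0("b", seq_len(n_b))),
                      type = rep(c(FALSE, TRUE), c(n_a, n_b)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
  m <- igraph::max_bipartite_match(g, types = igraph::V(g)$type,
                                   weights = igraph::E(g)$weight)$matching
  out <- rep(NA_integer_, n_b)
  for (j in seq_len(n_b)) {
    mt <- m[[paste0("b", j)]]
    if (!is.na(mt)) out[j] <- as.integer(sub("a", "", mt))
  }
  out
}

#' Track identity accuracy against simulator ground truth
#'
#' For every ground-truth (cell, frame) position the nearest detection within
#' `tol` is taken; a cell's reference track is the track id it is assigned
#' most often. Accuracy is the fraction of assignments that agree with the
#' reference track, averaged over all matched (cell, frame) pairs — 100 means
#' every cell kept a single identity throughout.
#'
#' @param tracks tracked segmentation from [link_tracks()].
#' @param ground_truth the `ground_truth` element of a simulated movie.
#' @param tol match radius, um.
#' @return List with `accuracy_pct`, `n_matched`, `n_truth`.
#' @export
track_identity_accuracy <- function(tracks, ground_truth, tol = 10) {
  gt <- ground_truth$frames
  tab <- tracks$table
  hits <- data.frame(cell = integer(), track = integer())
  for (f in sort(unique(gt$frame))) {
    g <- gt[gt$frame == f, ]
    d <- tab[tab$frame == f, ]
    if (nrow(d) == 0) next
    for (k in seq_len(nrow(g))) {
      dist <- sqrt((d$x_um - g$x_um[k])^2 + (d$y_um - g$y_um[k])^2)
      i <- which.min(dist)
      if (dist[i] <= tol) {
        hits <- rbind(hits, data.frame(cell = g$cell_id[k], track = d$track_id[i]))
      }
    }
  }
  if (nrow(hits) == 0) return(list(accuracy_pct = NA_real_, n_matched = 0, n_truth = nrow(gt)))
  ok <- unlist(lapply(split(hits$track, hits$cell), function(tr) {
    ref <- as.integer(names(which.max(table(tr))))
    tr == ref
  }))
  list(accuracy_pct = 100 * mean(ok), n_matched = nrow(hits), n_truth = nrow(gt))
}
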