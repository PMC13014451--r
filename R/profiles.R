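# Structural analyses over labeled frames: contacts, hydration shells,
# hydrogen bonds, radial distribution functions, electron-density profiles.
# All spatial queries use per-pair minimum-image distances when the frame
# carries a periodic box, plain Euclidean distances otherwise.

.coords <- function(frame) cbind(frame$x, frame$y, frame$z)

# n_a x n_b distance matrix between row sets A and B (minimum image if box)
.pair_dist <- function(A, B, box = NULL) {
  d2 <- matrix(0, nrow(A), nrow(B))
  for (k in 1:3) {
    dk <- outer(A[, k], B[, k], "-")
    if (!is.null(box)) dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

.frame_conformable <- function(frames) {
  n <- nrow(frames[[1]])
  lab <- frames[[1]]$label
  for (fr in frames) {
    if (nrow(fr) != n || !identical(fr$label, lab)) {
      stop("frames must share atom count and label order")
    }
  }
  invisible(TRUE)
}

#' Native and non-native contact analysis
#'
#' A probe-partner atom pair is "in contact" when its distance is at or
#' below `cutoff`. Pairs in contact in the designated reference frame form
#' the native set; contacts outside it are non-native. Counts are averaged
#' over frames and rounded to the nearest integer for reporting; the mean
#' distance is the average over all contacting pair instances.
#'
#' @param frames list of conformable [mem_frame] objects.
#' @param probe_label component label of the probe (default "DRG").
#' @param reference_frame a [mem_frame] defining the native pair set.
#' @param cutoff contact distance (A, default 7).
#' @return object of class `contact_report`: data.frame with one row per
#'   partner component label and columns `native`, `nonnative`,
#'   `mean_min_distance`.
#' @export
count_contacts <- function(frames, probe_label = "DRG", reference_frame,
                           cutoff = 7.0) {
  .frame_conformable(c(list(reference_frame), frames))
  p_idx <- which(reference_frame$label == probe_label)
  if (!length(p_idx)) stop("probe label ", probe_label, " absent from frames")
  o_idx <- which(reference_frame$label != probe_label)
  labels <- reference_frame$label[o_idx]
  ref_d <- .pair_dist(.coords(reference_frame)[p_idx, , drop = FALSE],
                      .coords(reference_frame)[o_idx, , drop = FALSE],
                      frame_box(reference_frame))
  native_set <- ref_d <= cutoff
  ulab <- sort(unique(labels))
  nat <- nonnat <- stats::setNames(numeric(length(ulab)), ulab)
  dist_sum <- dist_n <- stats::setNames(numeric(length(ulab)), ulab)
  for (fr in frames) {
    d <- .pair_dist(.coords(fr)[p_idx, , drop = FALSE],
                    .coords(fr)[o_idx, , drop = FALSE], frame_box(fr))
    contact <- d <= cutoff
    for (lb in ulab) {
      cols <- labels == lb
      cc <- contact[, cols, drop = FALSE]
      nn <- native_set[, cols, drop = FALSE]
      nat[lb] <- nat[lb] + sum(cc & nn)
      nonnat[lb] <- nonnat[lb] + sum(cc & !nn)
      dist_sum[lb] <- dist_sum[lb] + sum(d[, cols, drop = FALSE][cc])
      dist_n[lb] <- dist_n[lb] + sum(cc)
    }
  }
  nf <- length(frames)
  out <- data.frame(
    label = ulab,
    native = round(nat / nf),
    nonnative = round(nonnat / nf),
    mean_min_distance = ifelse(dist_n > 0, dist_sum / dist_n, NA_real_),
    row.names = NULL
  )
  structure(out, class = c("contact_report", "data.frame"))
}

#' Hydration-shell population per umbrella window
#'
#' Counts water molecules (their oxygen atoms, label WAT and element O)
#' within `threshold` of any probe atom, per frame; reports the per-window
#' mean with a +-1 sigma band from the frame-by-frame fluctuations
#' (population standard deviation).
#'
#' @param frames_by_window named list: one entry per window, name = bias
#'   center (A), value = list of [mem_frame] objects.
#' @param probe_label probe component label (default "DRG").
#' @param threshold hydration distance (A, default 3).
#' @return a [zprofile]: z = bias centers, values = mean water count,
#'   stderr = 1 sigma band.
#' @export
hydration_profile <- function(frames_by_window, probe_label = "DRG",
                              threshold = 3.0) {
  if (threshold <= 0) stop("threshold must be > 0")
  centers <- as.numeric(names(frames_by_window))
  if (anyNA(centers)) stop("frames_by_window names must be bias centers")
  ord <- order(centers)
  stats_w <- lapply(frames_by_window, function(frames) {
    counts <- vapply(frames, function(fr) {
      p <- which(fr$label == probe_label)
      if (!length(p)) stop("probe label ", probe_label, " absent from frame")
      w <- which(fr$label == "WAT" & fr$element == "O")
      if (!length(w)) return(0)
      d <- .pair_dist(.coords(fr)[p, , drop = FALSE],
                      .coords(fr)[w, , drop = FALSE], frame_box(fr))
      sum(apply(d, 2, min) <= threshold)
    }, 0)
    c(mean = mean(counts), sigma = sqrt(mean((counts - mean(counts))^2)))
  })
  m <- vapply(stats_w, `[`, numeric(2), 1:2)
  zprofile(centers[ord], m["mean", ord], stderr = m["sigma", ord],
           unit = "waters")
}

#' Geometric hydrogen-bond analysis of one frame
#'
#' A donor (heavy, H) pair and an acceptor form a bond when the
#' heavy-acceptor distance is at most `d_max` and the donor-H...acceptor
#' angle (at the hydrogen) is at least `angle_min` degrees. Bonds are
#' tallied per partner component label (the non-probe side when the probe
#' participates), with donor/acceptor role counts for the probe.
#'
#' @param frame a [mem_frame].
#' @param donors data.frame with integer columns `heavy` and `h` (atom
#'   indices into `frame`); every `h` must exist and be a hydrogen.
#' @param acceptors integer vector of acceptor atom indices.
#' @param d_max heavy-acceptor cutoff (A, default 3.5).
#' @param angle_min angular cutoff (degrees, default 135).
#' @param probe_label component label whose donor/acceptor roles are
#'   tallied (default "DRG").
#' @return object of class `hbond_report`: data.frame with columns `label`,
#'   `n_bonds`, `probe_as_donor`, `probe_as_acceptor`, `mean_distance`,
#'   `mean_angle`.
#' @export
hydrogen_bonds <- function(frame, donors, acceptors, d_max = 3.5,
                           angle_min = 135, probe_label = "DRG") {
  donors <- as.data.frame(donors)
  if (!all(c("heavy", "h") %in% names(donors))) {
    stop("donors needs columns heavy and h")
  }
  n <- nrow(frame)
  if (anyNA(donors$h) || any(donors$h < 1 | donors$h > n)) {
    stop("donor pair with missing hydrogen")
  }
  if (any(frame$element[donors$h] != "H")) {
    stop("donor h indices must point at hydrogen atoms")
  }
  co <- .coords(frame); box <- frame_box(frame)
  rows <- list()
  for (i in seq_len(nrow(donors))) {
    hv <- donors$heavy[i]; hh <- donors$h[i]
    for (ac in acceptors) {
      if (ac == hv) next
      dvec <- function(a, b) {
        d <- co[a, ] - co[b, ]
        if (!is.null(box)) d <- d - box * round(d / box)
        d
      }
      dHA <- dvec(ac, hv)
      r <- sqrt(sum(dHA^2))
      if (r > d_max) next
      v1 <- dvec(hv, hh); v2 <- dvec(ac, hh)
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang < angle_min) next
      donor_is_probe <- frame$label[hv] == probe_label
      acc_is_probe <- frame$label[ac] == probe_label
      partner <- if (donor_is_probe) frame$label[ac] else
                 if (acc_is_probe) frame$label[hv] else frame$label[ac]
      rows[[length(rows) + 1L]] <- data.frame(
        label = partner, distance = r, angle = ang,
        probe_donor = donor_is_probe, probe_acceptor = acc_is_probe)
    }
  }
  if (!length(rows)) {
    out <- data.frame(label = character(0), n_bonds = integer(0),
                      probe_as_donor = integer(0), probe_as_acceptor = integer(0),
                      mean_distance = numeric(0), mean_angle = numeric(0))
    return(structure(out, class = c("hbond_report", "data.frame")))
  }
  all <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(split(all, all$label), function(g) {
    data.frame(label = g$label[1], n_bonds = nrow(g),
               probe_as_donor = sum(g$probe_donor),
               probe_as_acceptor = sum(g$probe_acceptor),
               mean_distance = mean(g$distance), mean_angle = mean(g$angle))
  }))
  rownames(out) <- NULL
  structure(out, class = c("hbond_report", "data.frame"))
}

#' Radial distribution function between two component labels
#'
#' g(r) on bin centers, normalized so an ideal gas gives 1. With a periodic
#' box, pair distances use the minimum image and the partner density is
#' N_b/V; `r_max` must not exceed half the smallest box length. Without a
#' box, the frame is treated as open and the partner density is taken from
#' `density` (atoms/A^3) or, failing that, estimated from the axis-aligned
#' bounding box of the partner coordinates.
#'
#' @param frames list of [mem_frame] objects.
#' @param label_a,label_b center and partner component labels.
#' @param r_max maximum distance (A).
#' @param bin_width radial bin width (A, default 0.1).
#' @param density optional partner number density for open frames.
#' @return a [zprofile] over r with unit "g(r)".
#' @export
rdf <- function(frames, label_a, label_b, r_max, bin_width = 0.1,
                density = NULL) {
  breaks <- seq(0, r_max, by = bin_width)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  B <- length(breaks) - 1L
  counts <- numeric(B)
  norm <- 0
  for (fr in frames) {
    box <- frame_box(fr)
    ia <- which(fr$label == label_a)
    ib <- which(fr$label == label_b)
    if (!length(ia)) stop("label ", label_a, " absent from frame")
    if (!length(ib)) next
    if (!is.null(box) && r_max > min(box) / 2) {
      stop("r_max exceeds half the smallest box length")
    }
    d <- .pair_dist(.coords(fr)[ia, , drop = FALSE],
                    .coords(fr)[ib, , drop = FALSE], box)
    if (label_a == label_b) d[cbind(seq_along(ia), seq_along(ia))] <- Inf
    d <- d[d <= r_max]
    idx <- findInterval(d, breaks, rightmost.closed = TRUE)
    counts <- counts + tabulate(idx, nbins = B)
    rho <- if (!is.null(box)) {
      length(ib) / prod(box)
    } else if (!is.null(density)) {
      density
    } else {
      bb <- apply(.coords(fr)[ib, , drop = FALSE], 2, range)
      vol <- prod(pmax(bb[2, ] - bb[1, ], 1e-12))
      length(ib) / vol
    }
    norm <- norm + length(ia) * rho
  }
  centers <- (head(breaks, -1) + tail(breaks, -1)) / 2
  if (norm == 0) return(zprofile(centers, numeric(B), unit = "g(r)"))
  shell <- 4 / 3 * pi * (breaks[-1]^3 - head(breaks, -1)^3)
  zprofile(centers, counts / (norm * shell), unit = "g(r)")
}

#' Per-component electron-density profile along z
#'
#' Each atom contributes its element's electron count to the z bin holding
#' it; densities are electrons per A^3 (bin volume = `area` x bin height),
#' averaged over frames. The per-component profiles partition the all-atom
#' profile exactly.
#'
#' @param frames list of [mem_frame] objects.
#' @param z_breaks bin edges (A); default 1 A bins spanning the frames.
#' @param area lateral area (A^2); defaults to the box cross-section when a
#'   box is present.
#' @return object of class `density_profile_set`: `z` (bin centers),
#'   `densities` (named list of per-label vectors plus `"ALL"`), `area`,
#'   `bin_width`, `total_electrons` (per-frame average).
#' @export
electron_density <- function(frames, z_breaks = NULL, area = NULL) {
  els <- unique(unlist(lapply(frames, function(fr) fr$element)))
  unknown <- setdiff(els, names(.electron_counts))
  if (length(unknown)) {
    stop("no electron count for element(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(area)) {
    box <- frame_box(frames[[1]])
    if (is.null(box)) stop("area must be given for frames without a box")
    area <- box[1] * box[2]
  }
  if (is.null(z_breaks)) {
    zr <- range(unlist(lapply(frames, function(fr) fr$z)))
    z_breaks <- seq(floor(zr[1]), ceiling(zr[2]) + 1, by = 1)
  }
  B <- length(z_breaks) - 1L
  labs <- sort(unique(unlist(lapply(frames, function(fr) fr$label))))
  acc <- stats::setNames(rep(list(numeric(B)), length(labs) + 1L),
                         c(labs, "ALL"))
  total_e <- 0
  for (fr in frames) {
    e <- .electron_counts[fr$element]
    idx <- findInterval(fr$z, z_breaks, rightmost.closed = TRUE)
    ok <- idx >= 1L & idx <= B
    total_e <- total_e + sum(e)
    for (lb in labs) {
      sel <- ok & fr$label == lb
      if (any(sel)) {
        acc[[lb]] <- acc[[lb]] +
          vapply(seq_len(B), function(b) sum(e[sel & idx == b]), 0)
      }
    }
  }
  vols <- area * diff(z_breaks)
  nf <- length(frames)
  dens <- lapply(acc[labs], function(a) a / (vols * nf))
  dens$ALL <- Reduce(`+`, dens[labs])
  structure(list(z = (head(z_breaks, -1) + tail(z_breaks, -1)) / 2,
                 densities = dens, area = area,
                 bin_heights = diff(z_breaks),
                 total_electrons = total_e / nf),
            class = "density_profile_set")
}

#' @export
print.density_profile_set <- function(x, ...) {
  cat(sprintf(
    "Electron density: %d bins, components %s; %.0f electrons/frame\n",
    length(x$z), paste(setdiff(names(x$densities), "ALL"), collapse = ","),
    x$total_electrons))
  invisible(x)
}

#' @export
as.data.frame.density_profile_set <- function(x, ...) {
  d <- data.frame(z_angstrom = x$z)
  for (nm in names(x$densities)) d[[paste0("e_per_A3_", nm)]] <- x$densities[[nm]]
  d
}
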