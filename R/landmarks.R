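#' Rigidly align a specimen to the standard measurement frame
#'
#' Translates the bill-tip to the origin and rotates so the chord (tip to
#' proximal culmen endpoint) lies along +x and the sagittal plane maps to the
#' x-z plane with the culmen bulging toward +z. This is the frame in which
#' distal "millimeters" (sharpness slabs) and the dorsal-view included angle
#' are measured.
#'
#' @param specimen A `bill_specimen` with contour curves.
#' @return The transformed specimen.
#' @export
align_to_axis <- function(specimen) {
  culmen <- specimen$contours$culmen
  tip <- culmen[1, ]
  prox <- culmen[nrow(culmen), ]
  chord <- prox - tip
  cl <- sqrt(sum(chord^2))
  if (cl < 1e-9) stop("coincident tip and proximal culmen points")
  u <- chord / cl
  # dorsal direction: dominant culmen residual orthogonal to the chord
  resid <- sweep(culmen, 2, tip) - outer(as.vector(sweep(culmen, 2, tip) %*% u), u)
  sv <- svd(resid)
  w <- sv$v[, 1]
  w <- w - sum(w * u) * u
  wn <- sqrt(sum(w^2))
  if (wn < 1e-12) {
    w <- c(0, 0, 1) - u[3] * u            # straight culmen: any normal will do
    w <- w / sqrt(sum(w^2))
  } else {
    w <- w / wn
    mid <- culmen[ceiling(nrow(culmen) / 2), ] - tip
    if (sum((mid - sum(mid * u) * u) * w) < 0) w <- -w
  }
  yhat <- c(w[2] * u[3] - w[3] * u[2],
            w[3] * u[1] - w[1] * u[3],
            w[1] * u[2] - w[2] * u[1])
  rot <- rbind(u, yhat, w)
  dimnames(rot) <- NULL
  transform_specimen(specimen, rotation = rot,
                     translation = as.vector(-rot %*% tip))
}

#' Resample a polyline to equally spaced points in arc length
#'
#' @param curve An `n x 3` matrix of ordered points (tip-first).
#' @param n Number of output points (>= 2); endpoints are preserved exactly.
#' @return An `n x 3` matrix.
#' @export
resample_curve <- function(curve, n = 60L) {
  if (n < 2L) stop("n must be >= 2")
  if (nrow(curve) < 2L) stop("curve needs at least 2 points")
  seg <- sqrt(rowSums(diff(curve)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) stop("zero-length curve")
  target <- seq(0, total, length.out = n)
  out <- matrix(0, n, 3)
  for (d in 1:3) out[, d] <- stats::approx(cum, curve[, d], xout = target,
                                           ties = "ordered")$y
  out[1, ] <- curve[1, ]
  out[n, ] <- curve[nrow(curve), ]
  out
}

#' Assemble the fixed-landmark + semilandmark configuration
#'
#' Merges the three resampled contour curves into one ordered configuration:
#' the shared bill-tip point is kept exactly once (assigned to the midline
#' set), curve endpoints are homologous fixed landmarks, and all interior
#' points are sliding semilandmarks with within-curve tangent neighbors.
#' With `n` points per curve the configuration has `3n - 2` points; the
#' default protocol (n = 60) gives 178 points, 4 fixed and 174 sliding.
#' Left and right tomium points are paired by within-curve index; culmen
#' points (including the tip) form the unpaired midline set.
#'
#' @param curves Named list with `culmen`, `left_tomium`, `right_tomium`
#'   matrices of identical row count, sharing their first (tip) point.
#' @param tol Tip-coincidence tolerance, mm.
#' @return A `landmark_config`: `coords` (k x 3), `fixed_idx`, `semi_idx`,
#'   `curve` (per-point curve label and sliding neighbors), `pair`
#'   (involution; `NA` on the midline), `midline_idx`.
#' @export
assemble_configuration <- function(curves, tol = 1e-6) {
  need <- c("culmen", "left_tomium", "right_tomium")
  if (!all(need %in% names(curves))) stop("curves must be named ", paste(need, collapse = ", "))
  n <- nrow(curves$culmen)
  if (nrow(curves$left_tomium) != n || nrow(curves$right_tomium) != n)
    stop("all three curves must have the same number of points")
  if (n < 2L) stop("curves need at least 2 points")
  tip <- curves$culmen[1, ]
  for (nm in c("left_tomium", "right_tomium")) {
    if (sqrt(sum((curves[[nm]][1, ] - tip)^2)) > tol)
      stop("curve '", nm, "' does not share the bill-tip point")
  }
  k <- 3L * n - 2L
  coords <- rbind(curves$culmen,
                  curves$left_tomium[-1, , drop = FALSE],
                  curves$right_tomium[-1, , drop = FALSE])
  # row blocks: culmen 1..n, left n+1..2n-1, right 2n..3n-2
  left_row <- function(i) n + i - 1L    # within-curve index i in 2..n
  right_row <- function(i) 2L * n + i - 2L
  fixed_idx <- c(1L, n, left_row(n), right_row(n))
  semi_idx <- setdiff(seq_len(k), fixed_idx)

  label <- c(rep("culmen", n), rep("left_tomium", n - 1L),
             rep("right_tomium", n - 1L))
  prv <- nxt <- rep(NA_integer_, k)
  if (n > 2L) {
    ii <- 2:(n - 1L)                 # within-curve semilandmark indices
    prv[ii] <- ii - 1L; nxt[ii] <- ii + 1L
    prv[left_row(ii)] <- ifelse(ii == 2L, 1L, left_row(ii) - 1L)
    nxt[left_row(ii)] <- left_row(ii) + 1L
    prv[right_row(ii)] <- ifelse(ii == 2L, 1L, right_row(ii) - 1L)
    nxt[right_row(ii)] <- right_row(ii) + 1L
  }
  pair <- rep(NA_integer_, k)
  if (n >= 2L) {
    i2 <- 2:n
    pair[left_row(i2)] <- right_row(i2)
    pair[right_row(i2)] <- left_row(i2)
  }
  structure(list(coords = coords, fixed_idx = fixed_idx, semi_idx = semi_idx,
                 curve = data.frame(label = label, prev = prv, nxt = nxt),
                 pair = pair, midline_idx = 1:n),
            class = "landmark_config")
}

#' Build the landmark configuration of one specimen
#'
#' Resamples each contour to `n` points and assembles the configuration.
#'
#' @param specimen A `bill_specimen`.
#' @param n Points per curve (default 60, the standard protocol).
#' @return A `landmark_config`.
#' @export
specimen_configuration <- function(specimen, n = 60L) {
  curves <- lapply(specimen$contours, resample_curve, n = n)
  # resampling can move the first tomium point off the shared tip by only
  # floating error; snap to the culmen tip to preserve the invariant
  curves$left_tomium[1, ] <- curves$culmen[1, ]
  curves$right_tomium[1, ] <- curves$culmen[1, ]
  assemble_configuration(curves)
}

#' Write landmark configurations to CSV
#'
#' One row per point: specimen_id, point_index, role (fixed/semilandmark),
#' curve_label, x, y, z.
#'
#' @param configs Named list of `landmark_config` objects.
#' @param path Output CSV path.
#' @return `path` invisibly.
#' @export
write_landmarks_csv <- function(configs, path) {
  rows <- lapply(names(configs), function(id) {
    cfg <- configs[[id]]
    k <- nrow(cfg$coords)
    data.frame(specimen_id = id, point_index = seq_len(k),
               role = ifelse(seq_len(k) %in% cfg$fixed_idx,
                             "fixed", "semilandmark"),
               curve_label = cfg$curve$label,
               x = cfg$coords[, 1], y = cfg$coords[, 2], z = cfg$coords[, 3])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write configurations in TPS dialect
#'
#' Minimal TPS writer (LM3 blocks with ID lines) for interoperability with
#' morphometrics tools.
#'
#' @param configs Named list of `landmark_config` objects.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_landmarks_tps <- function(configs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(configs)) {
    cfg <- configs[[id]]
    writeLines(sprintf("LM3=%d", nrow(cfg$coords)), con)
    utils::write.table(format(cfg$coords, digits = 10), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    writeLines(sprintf("ID=%s", id), con)
  }
  invisible(path)
}
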