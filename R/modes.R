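# Internal degree-of-freedom displacement modes and finite configuration
# changes of the three-fragment model.

.mode_kinds <- c("attack", "search_in_plane", "search_out_of_plane",
                 "fragment_rotation", "fc_bend", "linker_scale")

#' Displacement mode of one internal degree of freedom
#'
#' A per-bead displacement field `d_k` (nm per unit amplitude).  Fields are
#' normalised so that the mean displacement magnitude over the moving beads is
#' 1 nm at unit amplitude: the fitted amplitude `a` is then directly the rms
#' displacement of the moving fragment in nm.
#'
#' @param vectors `N x 3` matrix of per-bead displacement vectors.
#' @param kind One of `r paste0('"', .mode_kinds, '"', collapse = ", ")`.
#' @param fragment Fragment the mode moves.
#' @param rmsd_per_unit_amplitude Mean |d_k| over moving beads at amplitude 1.
#' @return Object of class `displacement_mode`.
#' @export
displacement_mode <- function(vectors, kind, fragment,
                              rmsd_per_unit_amplitude = 1) {
  vectors <- as.matrix(vectors)
  stopifnot(ncol(vectors) == 3, kind %in% .mode_kinds)
  structure(list(vectors = vectors, kind = kind, fragment = fragment,
                 rmsd_per_unit_amplitude = rmsd_per_unit_amplitude),
            class = "displacement_mode")
}

#' @export
print.displacement_mode <- function(x, ...) {
  cat("displacement_mode:", x$kind, "of", x$fragment, "-",
      sum(rowSums(x$vectors^2) > 0), "moving beads\n")
  invisible(x)
}

#' Build the displacement field of one internal degree of freedom
#'
#' The supported motional patterns are
#' \describe{
#'   \item{attack}{radial stretch: every fragment bead displaced along the
#'     pivot-to-fragment-centre direction (exposes the Fab binding end).}
#'   \item{search_in_plane / search_out_of_plane}{first-order rigid rotation
#'     of the fragment about an axis through the pivot, normal to
#'     (respectively within) the three-fragment plane; bending motions that
#'     change relative fragment orientations.}
#'   \item{fragment_rotation}{first-order rigid rotation about the
#'     pivot-to-centre axis of the fragment.}
#'   \item{fc_bend}{first-order rotation of Fc about its hinge line.}
#'   \item{linker_scale}{radial displacement of the linker beads.}
#' }
#' Rotation-type fields are divergence-free rigid rotations: to first order
#' in amplitude they preserve distances from the rotation axis.
#'
#' @param model A [bead_model()].
#' @param kind Mode kind (see above).
#' @param fragment Fragment to move (ignored for `linker_scale`).
#' @return A [displacement_mode()], normalised to unit rmsd amplitude.
#' @export
make_displacement_mode <- function(model, kind = .mode_kinds, fragment = "Fab_l") {
  kind <- match.arg(kind)
  n <- nrow(model$positions)
  d <- matrix(0, n, 3)
  if (kind == "linker_scale") {
    idx <- which(model$labels == "linker")
    if (!length(idx)) stop("model has no linker beads")
    rel <- sweep(model$positions[idx, , drop = FALSE], 2, model$pivot)
    nr <- sqrt(rowSums(rel^2))
    if (any(nr < 1e-12)) stop("linker bead coincides with pivot")
    d[idx, ] <- rel / nr
    fragment <- "linker"
  } else if (kind == "fc_bend") {
    if (is.null(model$fc_hinge_axis)) stop("fc_hinge_axis is not set")
    idx <- which(model$labels == "Fc")
    axis <- model$fc_hinge_axis[2, ] - model$fc_hinge_axis[1, ]
    axis <- axis / sqrt(sum(axis^2))
    centre <- colMeans(model$fc_hinge_axis)
    rel <- sweep(model$positions[idx, , drop = FALSE], 2, centre)
    d[idx, ] <- t(apply(rel, 1, function(r) pracma::cross(axis, r)))
    fragment <- "Fc"
  } else {
    idx <- which(model$labels == fragment)
    if (!length(idx)) stop("fragment not present: ", fragment)
    com <- .fragment_com(model, fragment)
    arm <- com - model$pivot
    na <- sqrt(sum(arm^2))
    if (na < 1e-9) stop("degenerate geometry: fragment centre coincides with pivot")
    u <- arm / na
    if (kind == "attack") {
      d[idx, ] <- matrix(u, length(idx), 3, byrow = TRUE)
    } else {
      axis <- switch(kind,
        search_in_plane = .plane_normal(model),
        search_out_of_plane = {
          a <- pracma::cross(.plane_normal(model), u)
          a / sqrt(sum(a^2))
        },
        fragment_rotation = u)
      rel <- sweep(model$positions[idx, , drop = FALSE], 2, model$pivot)
      d[idx, ] <- t(apply(rel, 1, function(r) pracma::cross(axis, r)))
    }
  }
  rms <- mean(sqrt(rowSums(d[idx, , drop = FALSE]^2)))
  if (rms < 1e-12) stop("degenerate mode: zero displacement field")
  displacement_mode(d / rms, kind, fragment)
}

#' Configuration parameters for finite fragment rearrangement
#'
#' Finite (not first-order) rearrangement of the three-fragment geometry:
#' per-fragment in-plane and out-of-plane bend angles about the pivot,
#' per-fragment radial offsets along the pivot-to-centre line, an Fc bend
#' about the hinge line, and a linker scale factor.
#'
#' @param in_plane,out_plane Named numeric vectors of bend angles (rad) per
#'   fragment, e.g. `c(Fab_l = 0.2)`.
#' @param radial Named numeric vector of radial offsets (nm).
#' @param fc_bend Fc bend angle about the hinge line (rad).
#' @param linker_scale Linker scale factor (> 0).
#' @return Object of class `configuration_params`.
#' @export
configuration_params <- function(in_plane = numeric(), out_plane = numeric(),
                                 radial = numeric(), fc_bend = 0,
                                 linker_scale = 1) {
  stopifnot(linker_scale > 0)
  for (v in list(in_plane = in_plane, out_plane = out_plane, radial = radial)) {
    bad <- setdiff(names(v), c("Fc", "Fab_l", "Fab_m"))
    if (length(v) && (is.null(names(v)) || length(bad)))
      stop("per-fragment parameters must be named Fc/Fab_l/Fab_m; got: ",
           paste(bad, collapse = ", "))
  }
  ang <- c(in_plane, out_plane, fc_bend)
  if (length(ang) && any(ang <= -pi | ang > pi))
    stop("angles must lie in (-pi, pi]")
  structure(list(in_plane = in_plane, out_plane = out_plane, radial = radial,
                 fc_bend = fc_bend, linker_scale = linker_scale),
            class = "configuration_params")
}

#' Apply a finite configuration change to a bead model
#'
#' Fragments are moved rigidly: bent about the pivot (in-plane about the
#' plane normal, out-of-plane about the in-plane axis perpendicular to the
#' fragment arm), offset radially, the Fc optionally bent about its hinge
#' line, and the linker beads repositioned by linear interpolation between the
#' pivot and the (moved) fragment attachment directions, scaled by the linker
#' scale factor.  The three-fragment plane is taken from the configuration at
#' entry.  Bead count, contrasts and labels are preserved.
#'
#' @param model A [bead_model()].
#' @param params A [configuration_params()].
#' @return A new [bead_model()].
#' @export
apply_configuration <- function(model, params) {
  stopifnot(inherits(params, "configuration_params"))
  pos <- model$positions
  piv <- model$pivot
  nrm <- .plane_normal(model)
  hinge <- model$fc_hinge_axis
  frags <- .fragments(model)
  com0 <- lapply(frags, function(f) .fragment_com(model, f))
  names(com0) <- frags
  rot_frag <- function(idx, axis, angle, centre) {
    R <- .rotation_matrix(axis, angle)
    pos[idx, ] <<- sweep(sweep(pos[idx, , drop = FALSE], 2, centre) %*% t(R),
                         2, centre, `+`)
    if (!is.null(hinge) && any(model$labels[idx] == "Fc"))
      hinge <<- sweep(sweep(hinge, 2, centre) %*% t(R), 2, centre, `+`)
  }
  for (f in frags) {
    idx <- which(model$labels == f)
    arm <- com0[[f]] - piv
    u <- arm / sqrt(sum(arm^2))
    if (f %in% names(params$in_plane) && params$in_plane[[f]] != 0)
      rot_frag(idx, nrm, params$in_plane[[f]], piv)
    if (f %in% names(params$out_plane) && params$out_plane[[f]] != 0) {
      ax <- pracma::cross(nrm, u)
      ax <- ax / sqrt(sum(ax^2))
      rot_frag(idx, ax, params$out_plane[[f]], piv)
    }
    if (f %in% names(params$radial) && params$radial[[f]] != 0) {
      # translate along the current pivot -> centre line
      com_now <- colMeans(pos[idx, , drop = FALSE])
      un <- (com_now - piv) / sqrt(sum((com_now - piv)^2))
      pos[idx, ] <- sweep(pos[idx, , drop = FALSE], 2,
                          params$radial[[f]] * un, `+`)
      if (!is.null(hinge) && f == "Fc")
        hinge <- sweep(hinge, 2, params$radial[[f]] * un, `+`)
    }
  }
  if (params$fc_bend != 0) {
    if (is.null(hinge)) stop("fc_bend requested but fc_hinge_axis is not set")
    ax <- hinge[2, ] - hinge[1, ]
    rot_frag(which(model$labels == "Fc"), ax / sqrt(sum(ax^2)),
             params$fc_bend, colMeans(hinge))
  }
  # linker reconstruction: each linker bead follows its arm (the ray from
  # the pivot to its fragment's centre) rigidly - rotated with the arm,
  # stretched with the radial offset and the linker scale.  The disordered
  # linker contributes little to the scattering, so this straight-string
  # treatment suffices.
  lidx <- which(model$labels == "linker")
  if (length(lidx)) {
    out <- bead_model(pos, model$contrasts, model$labels, piv, hinge)
    arm_map <- lapply(frags, function(f) {
      a0 <- com0[[f]] - piv
      a1 <- .fragment_com(out, f) - piv
      n0 <- sqrt(sum(a0^2)); n1 <- sqrt(sum(a1^2))
      ax <- pracma::cross(a0, a1)
      R <- if (sqrt(sum(ax^2)) < 1e-12 * n0 * n1) diag(3) else
        .rotation_matrix(ax, acos(min(1, sum(a0 * a1) / (n0 * n1))))
      list(R = R, stretch = n1 / n0)
    })
    names(arm_map) <- frags
    for (i in lidx) {
      rel0 <- model$positions[i, ] - piv
      d0 <- vapply(frags, function(f) sum((rel0 - (com0[[f]] - piv) *
        sum(rel0 * (com0[[f]] - piv)) / sum((com0[[f]] - piv)^2))^2), numeric(1))
      am <- arm_map[[frags[which.min(d0)]]]
      pos[i, ] <- piv + params$linker_scale * am$stretch * drop(am$R %*% rel0)
    }
  }
  bead_model(pos, model$contrasts, model$labels, piv, hinge,
             masses = model$masses)
}

#' Contrast-weighted radius of gyration
#'
#' Root-mean-square distance of the beads from the contrast-weighted
#' centroid, weighted by scattering contrast.
#'
#' @param model A [bead_model()].
#' @return R_g in nm.
#' @export
radius_of_gyration <- function(model) {
  w <- model$contrasts
  if (sum(w) <= 0) stop("all-zero contrasts: R_g undefined")
  cen <- colSums(model$positions * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(model$positions, 2, cen)^2)) / sum(w))
}

#' Write a displacement-mode field to CSV
#'
#' Columns `bead_index,dx,dy,dz`.
#'
#' @param mode A [displacement_mode()].
#' @param path File path.
#' @export
write_mode <- function(mode, path) {
  utils::write.csv(data.frame(bead_index = seq_len(nrow(mode$vectors)),
                              dx = mode$vectors[, 1], dy = mode$vectors[, 2],
                              dz = mode$vectors[, 3]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
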