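# Coarse-grained three-fragment antibody model: bead models, internal
# degree-of-freedom displacement modes, and finite configuration changes.

#' Bead model of a multi-fragment protein
#'
#' Container for a coarse-grained scattering model: one bead per residue (or
#' any user-supplied bead set) with scattering contrasts, fragment labels, the
#' linker pivot (CPPC-motif centre) about which all internal modes act, and
#' optionally the Fc hinge axis (the two linker-attachment points on Fc).
#'
#' @param positions `N x 3` matrix of bead positions (nm).
#' @param contrasts Numeric vector of scattering contrasts per bead
#'   (arbitrary units).
#' @param labels Character vector of fragment labels, one of
#'   `"Fc"`, `"Fab_l"`, `"Fab_m"`, `"linker"`.
#' @param pivot Length-3 numeric, pivot point (nm).
#' @param fc_hinge_axis Optional `2 x 3` matrix: the two linker-attachment
#'   points on Fc defining the Fc bending line.
#' @param masses Optional numeric vector of bead masses (kDa).
#' @return Object of class `bead_model`.
#' @export
bead_model <- function(positions, contrasts, labels, pivot,
                       fc_hinge_axis = NULL, masses = NULL) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3, length(contrasts) == n, length(labels) == n,
            length(pivot) == 3)
  if (!all(is.finite(positions))) stop("bead positions must be finite")
  bad <- setdiff(unique(labels), c("Fc", "Fab_l", "Fab_m", "linker"))
  if (length(bad)) stop("unknown fragment labels: ", paste(bad, collapse = ", "))
  if (any(contrasts < 0)) stop("contrasts must be non-negative")
  centre <- colMeans(positions)
  rmax <- sqrt(max(rowSums(sweep(positions, 2, centre)^2)))
  if (sqrt(sum((pivot - centre)^2)) > rmax + 1e-9 && n > 1)
    stop("pivot lies outside the bounding sphere of the model")
  if (!is.null(fc_hinge_axis)) {
    fc_hinge_axis <- as.matrix(fc_hinge_axis)
    stopifnot(nrow(fc_hinge_axis) == 2, ncol(fc_hinge_axis) == 3)
  }
  structure(list(positions = positions, contrasts = as.numeric(contrasts),
                 labels = as.character(labels), pivot = as.numeric(pivot),
                 fc_hinge_axis = fc_hinge_axis, masses = masses),
            class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat("bead_model:", nrow(x$positions), "beads\n")
  print(table(x$labels))
  cat("pivot (nm):", signif(x$pivot, 4), "\n")
  cat("bounding radius (nm):", signif(bounding_radius(x), 4), "\n")
  invisible(x)
}

#' Bounding-sphere radius of a bead model about its pivot
#'
#' @param model A [bead_model()].
#' @param bead_radius Radius added per bead (nm); 0 treats beads as points.
#' @return Radius in nm.
#' @export
bounding_radius <- function(model, bead_radius = 0) {
  sqrt(max(rowSums(sweep(model$positions, 2, model$pivot)^2))) + bead_radius
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fragments <- function(model) setdiff(unique(model$labels), "linker")

.fragment_com <- function(model, fragment) {
  idx <- model$labels == fragment
  if (!any(idx)) stop("fragment not present: ", fragment)
  colMeans(model$positions[idx, , drop = FALSE])
}

# unit normal of the plane spanned by the three fragment centres of mass;
# recomputed from the current configuration whenever needed
.plane_normal <- function(model) {
  fr <- intersect(c("Fc", "Fab_l", "Fab_m"), unique(model$labels))
  if (length(fr) < 3) return(c(0, 0, 1))
  coms <- t(vapply(fr[1:3], function(f) .fragment_com(model, f), numeric(3)))
  n <- pracma::cross(coms[2, ] - coms[1, ], coms[3, ] - coms[1, ])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) return(c(0, 0, 1))
  n / nn
}

#' Build a synthetic Y-shaped three-fragment bead model
#'
#' Constructs an idealised IgG-like geometry: three spherical bead clusters
#' (two Fab arms at 0 and 120 degrees, Fc at 240 degrees in a common plane)
#' around a central pivot, connected by short straight linker bead strings.
#' With the default dimensions (fragment radius 4.2 nm, centre distance
#' 4.6 nm) the model's bounding sphere radius is 8.8 nm, matching a full-size
#' antibody.  Bead placement is uniform within each fragment sphere and
#' deterministic for a given seed.
#'
#' @param fragment_radius Fragment sphere radius (nm).
#' @param fragment_center_distance Distance pivot to fragment centre (nm).
#' @param beads_per_fragment Beads per fragment sphere.
#' @param seed Integer seed (bead placement).
#' @param linker_beads Beads per linker arm.
#' @param overlap_tol Warn if fragment spheres overlap by more than this (nm).
#' @return A [bead_model()] with attributes `fragment_radius` and
#'   `bounding_radius`.
#' @export
build_synthetic_ymodel <- function(fragment_radius = 4.2,
                                   fragment_center_distance = 4.6,
                                   beads_per_fragment = 40L,
                                   seed = 1L, linker_beads = 2L,
                                   overlap_tol = 0.5) {
  stopifnot(fragment_radius > 0, fragment_center_distance > 0,
            beads_per_fragment >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  angles <- c(Fab_l = 0, Fab_m = 120, Fc = 240) * pi / 180
  centres <- t(vapply(angles, function(a)
    fragment_center_distance * c(cos(a), sin(a), 0), numeric(3)))
  sep <- sqrt(sum((centres[1, ] - centres[2, ])^2))
  if (sep < 2 * fragment_radius - overlap_tol)
    warning("fragment spheres overlap by more than overlap_tol")
  sample_sphere <- function(n, R) {
    # uniform in ball: direction x radius ~ R u^(1/3)
    z <- matrix(stats::rnorm(3 * n), n, 3)
    z <- z / sqrt(rowSums(z^2))
    z * R * stats::runif(n)^(1 / 3)
  }
  pos <- NULL; lab <- NULL
  for (f in names(angles)) {
    if (beads_per_fragment == 1) {
      p <- matrix(centres[f, ], 1, 3)
    } else {
      p <- sweep(sample_sphere(beads_per_fragment, fragment_radius), 2,
                 centres[f, ], `+`)
    }
    pos <- rbind(pos, p)
    lab <- c(lab, rep(f, beads_per_fragment))
  }
  # straight linker strings pivot -> fragment-sphere attachment point
  for (f in names(angles)) {
    u <- centres[f, ] / sqrt(sum(centres[f, ]^2))
    attach <- centres[f, ] - fragment_radius * u
    if (sum(attach^2) < 1e-12) attach <- 0.1 * u
    frac <- seq_len(linker_beads) / (linker_beads + 1)
    pos <- rbind(pos, outer(frac, attach))
    lab <- c(lab, rep("linker", linker_beads))
  }
  # Fc hinge line: the two linker-attachment points on the Fc sphere,
  # offset perpendicular to the Fc arm within the fragment plane
  ufc <- centres["Fc", ] / sqrt(sum(centres["Fc", ]^2))
  perp <- pracma::cross(c(0, 0, 1), ufc)
  attach_fc <- centres["Fc", ] - fragment_radius * ufc
  hinge <- rbind(attach_fc + 0.6 * perp, attach_fc - 0.6 * perp)
  m <- bead_model(pos, rep(1, nrow(pos)), lab, pivot = c(0, 0, 0),
                  fc_hinge_axis = hinge)
  attr(m, "fragment_radius") <- fragment_radius
  attr(m, "bounding_radius") <- fragment_center_distance + fragment_radius
  m
}

# electrons per residue (in-chain, neutral) from atomic composition
.residue_electrons <- local({
  comp <- rbind(
    GLY = c(2, 3, 1, 1, 0),  ALA = c(3, 5, 1, 1, 0),  SER = c(3, 5, 1, 2, 0),
    PRO = c(5, 7, 1, 1, 0),  VAL = c(5, 9, 1, 1, 0),  THR = c(4, 7, 1, 2, 0),
    CYS = c(3, 5, 1, 1, 1),  LEU = c(6, 11, 1, 1, 0), ILE = c(6, 11, 1, 1, 0),
    ASN = c(4, 6, 2, 2, 0),  ASP = c(4, 5, 1, 3, 0),  GLN = c(5, 8, 2, 2, 0),
    GLU = c(5, 7, 1, 3, 0),  MET = c(5, 9, 1, 1, 1),  HIS = c(6, 7, 3, 1, 0),
    PHE = c(9, 9, 1, 1, 0),  ARG = c(6, 12, 4, 1, 0), TYR = c(9, 9, 1, 2, 0),
    TRP = c(11, 10, 2, 1, 0), LYS = c(6, 12, 2, 1, 0))
  drop(comp %*% c(6, 1, 7, 8, 16))
})

#' Coarse-grain a PDB structure to a residue-level bead model
#'
#' Reads a PDB structure (first model, altloc A), places one bead per residue
#' at the residue centre of geometry and assigns fragment labels from a
#' chain-to-fragment map.  Contrasts are proportional to the residue electron
#' count (default) or uniform.  The pivot is set to the centroid of the
#' C-alpha atoms of the CPPC hinge residues (`pivot_resno`, default 229-232 on
#' the heavy chains); if those residues are absent the overall centroid is
#' used with a message.
#'
#' @param pdb Path to a PDB file, or PDB-format text (detected by newline).
#' @param chain_to_fragment_map Named character vector mapping chain IDs to
#'   fragment labels, e.g. `c(A = "Fc", B = "Fab_l")`.
#' @param beads_per_residue Beads per residue (1 = centre of geometry;
#'   larger values split residue atoms by hierarchical clustering).
#' @param contrast `"electrons"` or `"uniform"`.
#' @param pivot_resno Residue numbers of the hinge motif.
#' @return A [bead_model()].
#' @export
load_pdb_coarse_grain <- function(pdb, chain_to_fragment_map,
                                  beads_per_residue = 1L,
                                  contrast = c("electrons", "uniform"),
                                  pivot_resno = 229:232) {
  contrast <- match.arg(contrast)
  stopifnot(beads_per_residue >= 1)
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    path <- pdb
  } else {
    path <- tempfile(fileext = ".pdb")
    writeLines(unlist(strsplit(paste(pdb, collapse = "\n"), "\n")), path)
    on.exit(unlink(path), add = TRUE)
  }
  s <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- s$atom
  at <- at[at$type == "ATOM" & (is.na(at$alt) | at$alt %in% c("", "A")), ]
  if (!nrow(at)) stop("no ATOM records in PDB input")
  missing_ch <- setdiff(names(chain_to_fragment_map), unique(at$chain))
  if (length(missing_ch))
    stop("mapped chain(s) not present in PDB: ", paste(missing_ch, collapse = ", "))
  key <- paste(at$chain, at$resno, at$insert %||% "")
  pos <- NULL; lab <- NULL; con <- NULL; resnos <- NULL; chains <- NULL; resids <- NULL
  for (k in unique(key)) {
    sel <- key == k
    xyz <- cbind(at$x[sel], at$y[sel], at$z[sel]) / 10  # Angstrom -> nm
    resid <- at$resid[sel][1]
    el <- if (resid %in% names(.residue_electrons)) .residue_electrons[[resid]]
          else mean(.residue_electrons)
    if (beads_per_residue == 1 || nrow(xyz) <= beads_per_residue) {
      centers <- matrix(colMeans(xyz), 1, 3)
    } else {
      cl <- stats::cutree(stats::hclust(stats::dist(xyz), method = "complete"),
                          k = beads_per_residue)
      centers <- t(vapply(seq_len(beads_per_residue), function(i)
        colMeans(xyz[cl == i, , drop = FALSE]), numeric(3)))
    }
    nb <- nrow(centers)
    pos <- rbind(pos, centers)
    con <- c(con, rep(if (contrast == "electrons") el / nb else 1, nb))
    chains <- c(chains, rep(at$chain[sel][1], nb))
    resnos <- c(resnos, rep(at$resno[sel][1], nb))
    resids <- c(resids, rep(resid, nb))
    lab <- c(lab, rep(NA_character_, nb))
  }
  lab <- unname(chain_to_fragment_map[chains])
  if (anyNA(lab)) {
    warning("unmapped residues assigned to nearest fragment")
    known <- !is.na(lab)
    if (!any(known)) stop("chain_to_fragment_map matches no chains")
    for (i in which(!known)) {
      d2 <- rowSums(sweep(pos[known, , drop = FALSE], 2, pos[i, ])^2)
      lab[i] <- lab[known][which.min(d2)]
    }
  }
  piv_sel <- resnos %in% pivot_resno & resids %in% c("CYS", "PRO")
  if (any(piv_sel)) {
    pivot <- colMeans(pos[piv_sel, , drop = FALSE])
  } else if (any(resnos %in% pivot_resno)) {
    pivot <- colMeans(pos[resnos %in% pivot_resno, , drop = FALSE])
  } else {
    message("hinge residues not found; using overall centroid as pivot")
    pivot <- colMeans(pos)
  }
  bead_model(pos, con, lab, pivot)
}

#' Write / read a bead model as a CSV table
#'
#' Columns `x,y,z,contrast,label` (nm); pivot and hinge stored as header
#' comment lines.
#'
#' @param model A [bead_model()].
#' @param path File path.
#' @return `write_bead_model` returns `path` invisibly; `read_bead_model`
#'   returns a [bead_model()].
#' @export
write_bead_model <- function(model, path) {
  hdr <- c(paste("# pivot_nm", paste(model$pivot, collapse = " ")),
           if (!is.null(model$fc_hinge_axis))
             paste("# fc_hinge_nm", paste(t(model$fc_hinge_axis), collapse = " ")))
  df <- data.frame(x = model$positions[, 1], y = model$positions[, 2],
                   z = model$positions[, 3], contrast = model$contrasts,
                   label = model$labels)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bead_model
#' @export
read_bead_model <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  pivot <- as.numeric(strsplit(sub("^# pivot_nm ", "", grep("pivot_nm", hdr, value = TRUE)), " ")[[1]])
  hinge <- NULL
  hl <- grep("fc_hinge_nm", hdr, value = TRUE)
  if (length(hl))
    hinge <- matrix(as.numeric(strsplit(sub("^# fc_hinge_nm ", "", hl), " ")[[1]]),
                    2, 3, byrow = TRUE)
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  bead_model(as.matrix(df[, c("x", "y", "z")]), df$contrast, df$label, pivot,
             fc_hinge_axis = hinge)
}
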