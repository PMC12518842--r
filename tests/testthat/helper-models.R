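# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# full-size synthetic antibody (Fig.-1-type dimensions)
ymodel_full <- function() fixture("ymodel_full", function()
  build_synthetic_ymodel(4.2, 4.6, 40L, seed = 101))

# small model for expensive fits
ymodel_small <- function() fixture("ymodel_small", function()
  build_synthetic_ymodel(4.2, 4.6, 10L, seed = 103))

water_env <- function() environment_conditions(298.15, 1.0, "custom")

# lattice-filled uniform sphere bead model (low texture noise)
lattice_sphere <- function(R = 3, spacing = R / 7.8) {
  g <- seq(-R + spacing / 2, R, by = spacing)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts <- pts[rowSums(pts^2) <= R^2, ]
  bead_model(pts, rep(1, nrow(pts)), rep("Fc", nrow(pts)), c(0, 0, 0))
}

attack_modes <- function(model)
  lapply(c("Fc", "Fab_l", "Fab_m"), function(f)
    make_displacement_mode(model, "attack", f))

# cached mode sets on the full model
modeset_attack_full <- function(Qg = seq(0.15, 2.4, by = 0.05))
  fixture("ms_attack_full", function()
    mode_set(ymodel_full(), attack_modes(ymodel_full()), Qg,
             amplitude = 0.5, lambda = 1, n_orientations = 601L))

modeset_fragrot_full <- function(Qg = seq(0.15, 2.4, by = 0.05))
  fixture("ms_fragrot_full", function()
    mode_set(ymodel_full(),
             lapply(c("Fc", "Fab_l", "Fab_m"), function(f)
               make_displacement_mode(ymodel_full(), "fragment_rotation", f)),
             Qg, amplitude = 0.5, lambda = 1, n_orientations = 601L))

# attack-mode set on the small model, on a grid covering the NSE Q range
modeset_fit <- function() fixture("fit_ms", function()
  mode_set(ymodel_small(), attack_modes(ymodel_small()),
           seq(0.15, 1.9, length.out = 30), n_orientations = 301L))

# NSE study conditions: instrument-like Q coverage and slow diffusion
nse_Q <- seq(0.2, 1.8, length.out = 10)
nse_D <- 0.03 + 0.005 * nse_Q

# toy two-chain PDB text (synthetic, for parser tests)
toy_pdb <- function() {
  rec <- function(serial, name, resid, chain, resno, x, y, z)
    sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            serial, name, resid, chain, resno, x, y, z)
  paste(rec(1, " CA ", "GLY", "A", 1, 0, 0, 0),
        rec(2, " CB ", "GLY", "A", 1, 2, 0, 0),
        rec(3, " CA ", "ALA", "A", 2, 10, 0, 0),
        rec(4, " CA ", "CYS", "B", 3, 0, 10, 0),
        rec(5, " CA ", "PRO", "B", 4, 0, 12, 0),
        "END", sep = "\n")
}

# write a bead model out as a synthetic PDB (one CA pseudo-atom per bead)
model_as_pdb <- function(model, path) {
  chains <- c(Fc = "A", Fab_l = "B", Fab_m = "C", linker = "L")
  lines <- vapply(seq_len(nrow(model$positions)), function(i)
    sprintf("ATOM  %5d  CA  GLY %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, chains[[model$labels[i]]], i,
            model$positions[i, 1] * 10, model$positions[i, 2] * 10,
            model$positions[i, 3] * 10), character(1))
  writeLines(c(lines, "END"), path)
  path
}
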