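# Shared fixtures, built in code and cached for the session. Sizes are kept
# small: the toy systems exercise every code path (periodicity, both species,
# both dipole variants) without condensed-phase realism.

.fx <- new.env(parent = emptyenv())

fx_cache <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# an 8-molecule periodic box with slightly perturbed geometry (bond stretches
# and orientations away from equilibrium, so charge-flow terms are active)
fx_perturbed_box <- function() fx_cache("pbox", function() {
  box <- generateWaterBox(8, seed = 3)
  set.seed(9)
  initialize(box, positions = positions(box) +
               matrix(rnorm(nAtoms(box) * 3, sd = 0.02), nAtoms(box), 3))
})

fx_fluct_backend <- function() fx_cache("bk_fluct", function()
  makeDipoleBackend(toyDipoleModel("fluctuating")))

fx_fixed_backend <- function() fx_cache("bk_fixed", function()
  makeDipoleBackend(toyDipoleModel("fixed")))

# small labelled dataset and a model trained on it (8-molecule boxes, cutoff
# 2.9 A because the 6.2 A cell bounds the minimum-image cutoff)
fx_dataset <- function() fx_cache("ds", function()
  splitDataset(makeLabelledDataset(6, 8, seed = 11), 0.75, seed = 1))

fx_model <- function() fx_cache("model", function()
  trainAPTModel(fx_dataset(), fx_hp(), trainConfig(maxEpochs = 30, seed = 1)))

fx_hp <- function() modelHyperparams(cutoff = 2.9, seed = 1)

# short NVE trajectory of a 4-molecule box with analytic APT labels per frame
fx_traj_apts <- function() fx_cache("traj_apts", function() {
  run <- generateTrajectory(generateWaterBox(4, seed = 5), dt = 0.5,
                            nSteps = 600, temperature = 300, seed = 5)
  apts <- lapply(frames(run$trajectory), computeAPTConfig,
                 backend = fx_fluct_backend(), method = "analytic")
  list(traj = run$trajectory, apts = apts)
})

# rotate a configuration (positions and cell) by an orthogonal matrix
rotate_config <- function(cfg, R) {
  atomicConfiguration(species(cfg), positions(cfg) %*% t(R),
                      cell = if (!is.null(cellMatrix(cfg)))
                        cellMatrix(cfg) %*% t(R) else NULL,
                      pbc = pbcFlags(cfg))
}

max_tensor_dev <- function(a, b) max(abs(a - b))
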