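# Shared fixtures, built lazily and cached for the whole test run.
# Sizes are deliberately small: a 48 px / 10 degree raster and a
# 400-voxel population keep a full simulated session plus a trained
# autoencoder cheap while preserving all structural invariants.

.fix <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (!exists(name, envir = .fix, inherits = FALSE)) {
    assign(name, .fix_builders[[name]](), envir = .fix)
  }
  get(name, envir = .fix, inherits = FALSE)
}

.fix_builders <- list(
  grid48 = function() vf_grid(48, 48, 10),
  letters48 = function() letter_set(fixture("grid48")),
  hrf3 = function() hrf_double_gamma(tr = 3),
  pop400 = function() sample_population(400, ecc_max = 5, seed = 42),
  design1 = function() session_design(seed = 7),
  session400 = function() {
    generate_session(fixture("pop400"), fixture("design1"), fixture("letters48"),
                     fixture("hrf3"), seed = 11)
  },
  pset400 = function() extract_trial_patterns(fixture("session400")),
  perc400 = function() average_letter_patterns(fixture("pset400"), "perception"),
  imag400 = function() average_letter_patterns(fixture("pset400"), "imagery"),
  ae400 = function() {
    train_autoencoder(pattern_matrix(fixture("perc400")), seed = 13)
  },
  w400 = function() encoding_matrix(fixture("pop400"), fixture("grid48")),
  proj400 = function() projection_matrix(fixture("w400"))
)

# small encoding matrix built by hand (bypasses the Gaussian constructor)
manual_encoding_matrix <- function(w, grid) {
  structure(w, grid = grid, voxels = seq_len(nrow(w)),
            class = c("encoding_matrix", "matrix", "array"))
}
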