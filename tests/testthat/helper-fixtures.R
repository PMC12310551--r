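# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# A tetrahedron with its base centered below the origin.
tetra_mesh <- function(scale = 1, shift = c(0, 0, 0)) {
  V <- rbind(c(-1, -1, -1), c(1, -1, -1), c(0, -1, 1), c(0, 1, 0)) * scale
  V <- sweep(V, 2L, shift, "+")
  F <- rbind(c(1, 2, 3), c(1, 2, 4), c(2, 3, 4), c(1, 3, 4))
  tri_mesh(V, F)
}

# n_tri random disconnected triangles inside a shell around the origin.
random_triangle_soup <- function(n_tri, seed, lo = 2, hi = 6) {
  set.seed(seed)
  ctr <- matrix(runif(3 * n_tri, -1, 1), ncol = 3L)
  ctr <- ctr / sqrt(rowSums(ctr^2)) * runif(n_tri, lo, hi)
  V <- ctr[rep(seq_len(n_tri), each = 3L), ] +
    matrix(runif(9 * n_tri, -0.5, 0.5), ncol = 3L)
  tri_mesh(V, matrix(seq_len(3L * n_tri), ncol = 3L, byrow = TRUE))
}

# Tiny random morphable model with K targets of shared topology.
toy_model <- function(K = 2L, seed = 1L) {
  set.seed(seed)
  base <- tetra_mesh()
  targets <- lapply(seq_len(K), function(i)
    tri_mesh(base$vertices + matrix(rnorm(12, 0, 0.2), ncol = 3L),
             base$faces))
  morphable_model(base, targets)
}

# Random template set with smooth-ish values away from the [0, 90] edges.
random_templates <- function(n_bins, K, seed = 1L, spread = 5) {
  set.seed(seed)
  g <- runif(n_bins, 30, 70)
  template_set(g,
               g + matrix(rnorm(n_bins * K, 0, spread), n_bins),
               g + matrix(rnorm(n_bins * K, 0, spread), n_bins))
}

default_eye <- function() {
  eye_pose(origin = c(0, 0, 0), forward = c(0, 0, 1), up = c(0, 1, 0),
           temporal = c(1, 0, 0))
}

# Hand-built occlusion map set (for extraction contract tests).
manual_maps <- function(rig, value = FALSE) {
  m <- matrix(value, rig$res, rig$res)
  structure(list(forward = m, up = m, down = m, temporal = m, nasal = m),
            class = "occlusion_maps", rig = rig)
}

# Mocked wide model: tiny tetrahedral head with `K` trivially perturbed
# morph targets, used for template-set bookkeeping at scale.
mock_wide_model <- function(K) {
  base <- tetra_mesh(scale = 20, shift = c(0, -40, 0))
  targets <- lapply(seq_len(K), function(i)
    tri_mesh(base$vertices + i * 1e-3, base$faces))
  morphable_model(base, targets, eye_anchor = c(0, 0, 0),
                  eye = default_eye())
}
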