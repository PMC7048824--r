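# Synthetic corpus generator: low-rank smooth shape variation plus i.i.d.
# vertex noise on the shared template triangulation, with sagittal
# mirroring for data augmentation.

# Evaluate code with a temporary RNG state so generation is deterministic
# given (seed, subject_index) without clobbering the caller's stream.
with_rng_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Smooth, ellipse-preserving raw displacement fields over the template
# vertices, stacked as 3V vectors (x block, y block, z block).  Each field
# shifts ring centers or scales ring semi-axes with station-smooth
# amplitudes, so deformed rings stay exact ellipses.
raw_mode_fields <- function(template) {
  topo <- template$topology
  dirs <- template$ring_dirs
  V <- nrow(template$vertices)
  s <- topo$s_values[topo$station_of_vertex]
  cs <- dirs$cs[topo$ring_of_vertex]
  sn <- dirs$sn[topo$ring_of_vertex]
  sgn <- ifelse(topo$side_of_vertex == "left", -1, 1)

  zeros <- numeric(V)
  stack <- function(dx, dz) c(dx, zeros, dz)
  cbind(
    stack(sin(pi * s) * cs, sin(pi * s) * sn),       # symmetric inflation
    stack(sgn * sin(pi * s) * cs, zeros),             # antisymmetric width
    stack(zeros, sin(2 * pi * s) * sn),               # 2nd-harmonic height
    stack(zeros, sin(pi * s)),                        # vertical bow
    stack(sin(2 * pi * s) * cs, zeros)                # 2nd-harmonic width
  )
}

n_available_modes <- function() 5L

#' Shape variation specification
#'
#' Describes the ground-truth low-rank variation used by the synthetic
#' corpus generator: `n_modes` orthonormal smooth displacement fields with
#' zero-mean normal weights of standard deviation `mode_sd` (mm), plus
#' i.i.d. per-vertex Gaussian residual noise of standard deviation
#' `noise_sd` (mm).
#'
#' @param n_modes Number of ground-truth modes (1 to 5).
#' @param mode_sd Per-mode weight standard deviations in mm, strictly
#'   decreasing.  The default `8 * 0.65^(0:(n_modes-1))` gives a dominant
#'   symmetric inflation mode followed by progressively weaker modes.
#' @param noise_sd Per-vertex residual standard deviation in mm.
#' @param seed Integer root seed; subject `i` uses stream `seed + i`.
#' @return An object of class `shape_variation`.
#' @export
shape_variation <- function(n_modes = 3,
                            mode_sd = 8 * 0.65^(seq_len(n_modes) - 1),
                            noise_sd = 0.05, seed = 1) {
  if (n_modes < 0 || n_modes > n_available_modes())
    stop("n_modes must be between 0 and ", n_available_modes())
  if (length(mode_sd) != n_modes)
    stop("mode_sd must have length n_modes")
  if (n_modes > 1 && any(diff(mode_sd) >= 0))
    stop("mode_sd must be strictly decreasing")
  if (any(mode_sd < 0) || noise_sd < 0)
    stop("mode_sd and noise_sd must be non-negative")
  structure(list(n_modes = as.integer(n_modes), mode_sd = mode_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "shape_variation")
}

# Orthonormal mode fields for a template (first n_modes columns of the
# QR-orthonormalised raw fields, signs fixed so the largest-magnitude
# component of each field is positive).
mode_field_matrix <- function(template, n_modes) {
  if (n_modes == 0) return(matrix(0, nrow = 3 * nrow(template$vertices), 0))
  raw <- raw_mode_fields(template)[, seq_len(n_modes), drop = FALSE]
  q <- qr.Q(qr(raw))
  for (k in seq_len(ncol(q))) {
    m <- which.max(abs(q[, k]))
    if (q[m, k] < 0) q[, k] <- -q[, k]
  }
  q
}

#' Generate one synthetic subject
#'
#' Draws mode weights `w_k ~ N(0, mode_sd_k^2)` and i.i.d. vertex noise from
#' the stream `seed + subject_index`, deforms the template accordingly and
#' recomputes per-station profiles from the deformed rings.
#'
#' @param template A [duct_template()].
#' @param spec A [shape_variation()].
#' @param subject_index Non-negative integer identifying the subject.
#' @return A `duct_geometry`.  The realised mode weights are stored in
#'   `$provenance$weights`.
#' @export
generate_subject <- function(template, spec, subject_index = 0) {
  stopifnot(inherits(template, "duct_template"),
            inherits(spec, "shape_variation"), subject_index >= 0)
  V <- nrow(template$vertices)
  fields <- mode_field_matrix(template, spec$n_modes)
  draw <- with_rng_seed(spec$seed + subject_index, {
    w <- if (spec$n_modes > 0) stats::rnorm(spec$n_modes, 0, spec$mode_sd)
         else numeric(0)
    noise <- if (spec$noise_sd > 0) stats::rnorm(3 * V, 0, spec$noise_sd)
             else numeric(3 * V)
    list(w = w, noise = noise)
  })
  disp <- draw$noise
  if (spec$n_modes > 0) disp <- disp + as.vector(fields %*% draw$w)
  vertices <- template$vertices + matrix(disp, ncol = 3)
  new_duct_geometry(vertices, template$topology, template$ring_dirs,
                    provenance = list(subject_index = subject_index,
                                      weights = draw$w,
                                      seed = spec$seed))
}

#' Generate a synthetic corpus
#'
#' @param template A [duct_template()].
#' @param spec A [shape_variation()].
#' @param n_subjects Number of subjects (>= 2).
#' @return A `duct_corpus`: members (all unmirrored), per-member mirrored
#'   flag, and provenance recording the generator parameters and seed.
#' @export
generate_corpus <- function(template, spec, n_subjects = 25) {
  if (n_subjects < 2)
    stop("n_subjects must be >= 2 (a shape model needs at least two members)")
  members <- lapply(seq_len(n_subjects) - 1L,
                    function(i) generate_subject(template, spec, i))
  structure(
    list(members = members,
         mirrored = rep(FALSE, n_subjects),
         provenance = list(
           n_subjects = n_subjects, seed = spec$seed,
           n_modes = spec$n_modes, mode_sd = spec$mode_sd,
           noise_sd = spec$noise_sd,
           n_stations = template$n_stations, n_ring = template$n_ring,
           length_mm = template$length_mm)),
    class = "duct_corpus")
}

#' @export
print.duct_corpus <- function(x, ...) {
  cat(sprintf("Duct corpus: %d members (%d mirrored), %d vertices each\n",
              length(x$members), sum(x$mirrored),
              nrow(x$members[[1]]$vertices)))
  invisible(x)
}

#' Mirror a geometry across the mid-sagittal plane
#'
#' Reflects the surface across x = 0 and re-indexes the vertices through
#' the template's left/right symmetry map, so the mirrored geometry keeps
#' the same triangulation and patch semantics (left patches now cover the
#' reflected right anatomy).  Applying the operation twice returns the
#' original exactly.
#'
#' @param g A `duct_geometry`.
#' @return The mirrored `duct_geometry`.
#' @export
mirror_subject <- function(g) {
  stopifnot(inherits(g, "duct_geometry"))
  if (is.null(g$symmetry_map))
    stop("geometry carries no left/right symmetry map; cannot mirror")
  v <- g$vertices[g$symmetry_map, , drop = FALSE]
  v[, 1] <- -v[, 1]
  new_duct_geometry(v, g$topology, g$ring_dirs,
                    provenance = c(g$provenance, list(mirrored = TRUE)))
}

#' Mirror-augment a corpus
#'
#' Appends to each member its sagittal mirror, doubling the corpus.  This
#' is the standard augmentation for bilateral anatomy and forces the mean
#' shape of the resulting model to be mirror-symmetric.
#'
#' @param corpus A `duct_corpus` with no already-mirrored member.
#' @return A `duct_corpus` with 2N members, each original followed by its
#'   mirror image.
#' @export
mirror_augment <- function(corpus) {
  stopifnot(inherits(corpus, "duct_corpus"))
  if (any(corpus$mirrored))
    stop("corpus is already mirror-augmented")
  n <- length(corpus$members)
  members <- vector("list", 2 * n)
  mirrored <- logical(2 * n)
  for (i in seq_len(n)) {
    members[[2 * i - 1]] <- corpus$members[[i]]
    members[[2 * i]] <- mirror_subject(corpus$members[[i]])
    mirrored[2 * i] <- TRUE
  }
  structure(list(members = members, mirrored = mirrored,
                 provenance = c(corpus$provenance,
                                list(mirror_augmented = TRUE))),
            class = "duct_corpus")
}
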