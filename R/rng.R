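# Seed plumbing: every generator is a pure function of (config, seed).
# Sub-seeds are derived from the master seed by a stable string hash so that
# (annotator, case, session) streams are reproducible yet independent.

with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Polynomial rolling hash mod (2^31 - 1); inputs are pasted with a separator
# so ("a", 12) and ("a1", 2) cannot collide.
subseed <- function(master, ...) {
  s <- paste(c(master, ...), collapse = "|")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 65599 + b) %% 2147483647
  as.integer(h)
}

# Smooth band-limited random field on the unit sphere: a fixed sum of cosine
# modes with random directions and phases. `amp_sd` is the field's standard
# deviation over random directions (each mode contributes amp^2/2).
radial_field <- function(amp_sd, freq, n_modes = 6L, seed = 1L) {
  pars <- with_seed(seed, {
    w <- matrix(rnorm(n_modes * 3L), n_modes, 3L)
    w <- w / sqrt(rowSums(w^2))
    list(w = w, phase = runif(n_modes, 0, 2 * pi))
  })
  amp <- amp_sd * sqrt(2 / n_modes)
  function(U) {
    proj <- U %*% t(pars$w) * freq
    proj <- sweep(proj, 2, pars$phase, `+`)
    rowSums(cos(proj)) * amp
  }
}
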