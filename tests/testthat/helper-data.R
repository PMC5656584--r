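# Shared fixture builders.  Everything is generated in code; no files.

# Minimal expression set: `values` is genes x samples; metadata gives every
# sample to the parent unless strain ids are supplied.
make_expr <- function(values, strain = NULL, stress = "S01") {
  if (is.null(strain)) strain <- rep("parent", ncol(values))
  meta <- data.frame(sample_id = colnames(values), strain_id = strain,
                     evolution_stress = ifelse(strain == "parent", "none",
                                               stress),
                     assay_stress = stress,
                     replicate = stats::ave(seq_len(ncol(values)), strain,
                                            FUN = seq_along))
  expression_set(values, meta)
}

rand_mat <- function(n, m, prefix_r = "g", prefix_c = "s", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(n * m), n, m,
         dimnames = list(sprintf("%s%02d", prefix_r, seq_len(n)),
                         sprintf("%s%02d", prefix_c, seq_len(m))))
}

# Planted two-gene instance on a ten-gene pool: growth is an exact linear
# function of genes g01 and g02 (zero noise), so {g01, g02} is the unique
# fitness-1 optimum.
planted_pair_instance <- function(n_strains = 12, seed = 1) {
  set.seed(seed)
  X <- rand_mat(10, n_strains)
  dg <- cbind(A = 2 * X["g01", ] - X["g02", ] + 0.5,
              B = X["g01", ] + X["g02", ] - 0.2)
  rownames(dg) <- colnames(X)
  list(X = X, dg = dg, planted = c("g01", "g02"))
}

# Small synthetic study shared across tests (cached per session).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dataset(simulation_design(n_genes = 300),
                                 seed = 401, growth_noise_frac = 0.25)
    cache
  }
})
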