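# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite runs quickly on one CPU.

# A small fully synthetic study: stack, occurrences, evaluations.
tiny_study <- function(seed = 1, n_rows = 30, n_cols = 30, n_occ = 150,
                       n_eval = 80, ...) {
  truth <- synthetic_truth(seed = seed, ...)
  stack <- make_stack(truth, n_rows, n_cols)
  occ <- sample_occurrences(truth, stack, n = n_occ)
  eval_sites <- occ[rep_len(seq_len(n_occ), n_eval), ]
  evals <- simulate_dsr(truth, eval_sites)
  list(truth = truth, stack = stack, occ = occ,
       eval_sites = eval_sites, evals = evals)
}

# A hand-buildable population table for the filtering rules: every derived
# column is set directly so expectations are computable without the stack.
filter_populations <- function(n,
                               iar_dm, iar_dm_f = iar_dm,
                               texture = "Other", ec = 1,
                               elc = 1L, excluded = FALSE) {
  tibble::tibble(
    pop_id = sprintf("ID_%07d", seq_len(n)),
    taxon = "L. nigricans",
    lon = seq_len(n) / 100, lat = 40 + seq_len(n) / 100,
    iar_dm = rep_len(iar_dm, n),
    iar_dm_f = rep_len(iar_dm_f, n),
    texture_class = factor(rep_len(texture, n),
      levels = c("Clay", "Silty Clay", "Sandy Clay", "Silty Clay Loam", "Other")
    ),
    ec_topsoil = rep_len(ec, n),
    elc_category = rep_len(elc, n),
    elc_excluded = rep_len(excluded, n)
  )
}

# Cleanly separable two-class data for the calibration suite.
separable_records <- function(n = 120, seed = 42) {
  withr::with_seed(seed, {
    n_pos <- round(n / 4)
    y <- rep(c(TRUE, FALSE), c(n_pos, n - n_pos))
    tibble::tibble(
      resistant = y,
      v1 = ifelse(y, 10, 0) + rnorm(n, sd = 0.3),
      v2 = ifelse(y, -5, 5) + rnorm(n, sd = 0.3),
      v3 = rnorm(n)
    )
  })
}
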