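# Shared fixtures: all synthetic, built in code.

# Small 3-subject dataset: 1 dose + 6 plasma + 2 urine rows per subject.
make_toy_dataset <- function(n = 3, dose = 1000) {
  subjects <- data.frame(
    id = paste0("S", seq_len(n)),
    age = 30 + seq_len(n), height = 160 + seq_len(n),
    bw_before = 65 + seq_len(n), bw = 78 + seq_len(n),
    scr = 6 + 0.1 * seq_len(n), arm = "TXA1g",
    bleeding_volume = 900 + 10 * seq_len(n))
  doses <- data.frame(id = subjects$id, time = 0, amount = dose, tinf = 1)
  tt <- c(15, 30, 60, 120, 180, 360)
  obs_pl <- do.call(rbind, lapply(subjects$id, function(id)
    data.frame(id = id, time = tt, value = 100 * exp(-0.01 * tt),
               kind = "plasma", interval_start = NA_real_,
               urine_volume = NA_real_)))
  obs_ur <- do.call(rbind, lapply(subjects$id, function(id)
    data.frame(id = id, time = c(180, 360), value = c(250, 120),
               kind = "urine", interval_start = c(0, 180),
               urine_volume = c(0.4, 0.5))))
  pk_dataset(subjects, doses, rbind(obs_pl, obs_ur))
}

# The selected structural model with the published typical values.
final_spec <- function() structural_spec(2, elim_nonurinary = "first_order")

final_params <- function(p_urine = 0.54) {
  structural_params(CL = 0.077 * exp(0.0039 * 150), V1 = 9.25, Q = 0.32,
                    V2 = 9.49, p_urine = p_urine)
}

# Reported final-model uncertainty (RSE %) used in recovery scoring.
reported_rse <- c(CL = 7.3, V1 = 12.0, purine = 7.0, b_CL = 11.8,
                  b_V1 = 25.8)

# Short but honest SAEM schedule for repeated-fit test suites.
replicate_control <- function(...) {
  saem_control(n_explore = 250, n_smooth = 100, n_chains = 3,
               ll_draws = 1000, cond_iter = 80, ...)
}

extract_recovery <- function(fit) {
  c(CL = fit$theta[["CL"]], V1 = fit$theta[["V1"]],
    purine = fit$theta[["purine"]],
    b_CL = fit$betas[[1]]$value, b_V1 = fit$betas[[2]]$value)
}
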