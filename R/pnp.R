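# Plug-and-play ADMM reconstruction: a physics data-fidelity term, a learned
# or denoiser-based prior pull, and a proximity term tying the object
# estimate to the untrained generator output; sequential theta / object /
# multiplier updates with a stagnation-based stopping rule.

#' ADMM configuration
#'
#' @param alpha prior-regularization weight (>= 0).
#' @param beta proximity weight (>= 0).
#' @param c_step steepest-descent step size for the object update (> 0).
#'   The default `NULL` resolves to `1 / (alpha + beta)`, which makes the
#'   explicit step the exact minimizer of the quadratic object sub-problem
#'   and keeps the multiplier recursion contractive.
#' @param tol stopping tolerance; the loop stops early when the largest of
#'   the three sub-objective stagnation residuals stays at or below
#'   `tol / 3` for five consecutive epochs. `tol = 0` disables the
#'   stagnation rule so the epoch budget governs (the usual protocol for
#'   noiseless simulated data, where overfitting is not a concern).
#' @param max_epochs outer iteration cap.
#' @param inner_theta_steps gradient steps on the network per outer epoch.
#' @param theta_lr Adam learning rate for the network update.
#' @param multiplier_sign `"residual"` updates the multiplier with the
#'   splitting residual `uo - R(uo)` (default); `"sum"` uses `uo + R(uo)`
#'   for literal replication of the printed update.
#' @param net_input `"initial"` feeds the generator the fixed initial
#'   backprojection uo0 every epoch (the deep-image-prior anchoring;
#'   default), `"current"` feeds the evolving object estimate uo^k.
#' @param seed seed for the generator initialization and any stochastic
#'   component.
#' @return An object of class `admm_config`.
#' @export
admm_config <- function(alpha = 0.5, beta = 0.5, c_step = NULL, tol = 1e-3,
                        max_epochs = 700, inner_theta_steps = 1,
                        theta_lr = 0.01, multiplier_sign = c("residual", "sum"),
                        net_input = c("initial", "current"), seed = 1) {
  if (is.null(c_step)) c_step <- 1 / max(alpha + beta, .Machine$double.eps)
  stopifnot(alpha >= 0, beta >= 0, c_step > 0, tol >= 0, max_epochs >= 1,
            inner_theta_steps >= 0)
  structure(
    list(alpha = alpha, beta = beta, c_step = c_step, tol = tol,
         max_epochs = as.integer(max_epochs),
         inner_theta_steps = as.integer(inner_theta_steps),
         theta_lr = theta_lr, multiplier_sign = match.arg(multiplier_sign),
         net_input = match.arg(net_input), seed = as.integer(seed)),
    class = "admm_config"
  )
}

#' Build the prior bundle for plug-and-play reconstruction
#'
#' Assembles the high-resolution ingredients of the loss: the upsampled
#' hologram `I_tau` (bicubic upsampling of the measurement in every mode),
#' the prior phase `phi_tau`, and the trained complex object
#' `u_tau = mean(|uo0|) * exp(i * phi_tau)`.
#'
#' Modes: `"file"` takes `prior_phase` as supplied (the role played by an
#' externally trained super-resolution generator); `"tv"` total-variation
#' denoises the phase of the backpropagated upsampled hologram (the
#' denoiser-prior of regularization-by-denoising); `"bicubic"` bicubically
#' upsamples the backpropagated phase of the native-resolution hologram;
#' `"none"` disables the prior pull (plain deep-image-prior objective).
#'
#' @param holo a [hologram()].
#' @param mode one of `"none"`, `"tv"`, `"bicubic"`, `"file"`.
#' @param upsample_factor 1, 2 or 4.
#' @param prior_phase matrix of prior phase (radians) at the upsampled
#'   shape; required for `mode = "file"`.
#' @param z_mm reconstruction distance (mm) or `"auto"` for autofocus.
#' @param tv_lambda weight of the TV denoiser in `"tv"` mode.
#' @return An object of class `prior_bundle` with elements `phi_tau`,
#'   `I_tau` (a [hologram()] at the upsampled pitch), `u_tau`, `mode`,
#'   `upsample_factor`, `alpha_disabled`, `z_mm`.
#' @export
make_prior <- function(holo, mode = c("none", "tv", "bicubic", "file"),
                       upsample_factor = 1, prior_phase = NULL, z_mm = "auto",
                       tv_lambda = 0.2) {
  stopifnot(inherits(holo, "hologram"))
  mode <- match.arg(mode)
  if (!upsample_factor %in% c(1, 2, 4)) stop("`upsample_factor` must be 1, 2 or 4")
  if (identical(z_mm, "auto")) z_mm <- autofocus(holo)$z_star_mm
  up_int <- bicubic_upsample(holo$intensity, upsample_factor)
  up_int[up_int < 0] <- 0
  I_tau <- hologram(up_int, holo$z2_mm, holo$wavelength_nm,
                    holo$pitch_um / upsample_factor)
  uo0 <- backpropagate(I_tau, z_mm)
  phi_tau <- switch(
    mode,
    none = matrix(0, nrow(up_int), ncol(up_int)),
    tv = tv_denoise(Arg(uo0$values), lambda = tv_lambda),
    bicubic = bicubic_upsample(Arg(backpropagate(holo, z_mm)$values),
                               upsample_factor),
    file = {
      if (is.null(prior_phase))
        stop("mode = 'file' requires `prior_phase`")
      if (!all(dim(prior_phase) == dim(up_int)))
        stop("prior_phase shape (", paste(dim(prior_phase), collapse = "x"),
             ") does not match the upsampled grid (",
             paste(dim(up_int), collapse = "x"), ")")
      prior_phase
    }
  )
  u_tau <- mean(Mod(uo0$values)) * exp(1i * phi_tau)
  structure(
    list(phi_tau = phi_tau, I_tau = I_tau, u_tau = u_tau, mode = mode,
         upsample_factor = upsample_factor, alpha_disabled = (mode == "none"),
         z_mm = z_mm),
    class = "prior_bundle"
  )
}

#' Initialize the ADMM state
#'
#' The first object estimate is the backpropagation of the upsampled
#' hologram to the object plane; the multiplier field starts at exactly
#' zero, the epoch counter at zero, and the generator parameters are drawn
#' from the seeded initialization.
#'
#' @param holo a [hologram()] (used for metadata; the upsampled hologram in
#'   `prior` drives the fidelity term).
#' @param prior a [make_prior()] bundle.
#' @param gen_spec a [generator_spec()]; its seed is replaced by
#'   `config$seed` so one seed controls the run.
#' @param config an [admm_config()].
#' @return An object of class `admm_state`.
#' @export
initialize_admm <- function(holo, prior, gen_spec, config) {
  stopifnot(inherits(prior, "prior_bundle"), inherits(config, "admm_config"))
  gen_spec$seed <- config$seed
  uo0 <- backpropagate(prior$I_tau, prior$z_mm)
  structure(
    list(
      uo = uo0$values,
      uo0 = uo0$values,
      t_mult = matrix(0 + 0i, nrow(uo0$values), ncol(uo0$values)),
      theta = init_generator(gen_spec),
      opt = adam_init(),
      k = 0L,
      z_mm = prior$z_mm,
      pitch_um = prior$I_tau$pitch_um,
      wavelength_nm = holo$wavelength_nm,
      config = config,
      loss_hist = list(),
      sub_obj_hist = list(),
      lr_scale = 1
    ),
    class = "admm_state"
  )
}

# The generator input under the configured anchoring.
net_input_of <- function(state, config) {
  if (identical(config$net_input, "current")) state$uo else state$uo0
}

# Complex field <-> two-channel helpers.
c2ch <- function(u) cbind(as.vector(Re(u)), as.vector(Im(u)))
ch2c <- function(x, nr, nc) matrix(complex(real = x[, 1], imaginary = x[, 2]), nr, nc)

# Forward hologram operator H on the reconstruction grid and the Wirtinger
# gradient of the fidelity term 1/2 || |P_z(v)|^2 - I ||^2 with respect to
# conj(v): P_{-z}((|V|^2 - I) * V).
fidelity_and_grad <- function(v, I_tau, pitch_um, wavelength_nm, z_mm,
                              want_grad = TRUE) {
  f <- complex_field(v, pitch_um, wavelength_nm)
  V <- angular_spectrum_propagate(f, z_mm)$values
  resid <- Mod(V)^2 - I_tau
  out <- list(value = 0.5 * sum(resid^2))
  if (want_grad) {
    g <- complex_field(resid * V, pitch_um, wavelength_nm)
    out$grad_conj <- angular_spectrum_propagate(g, -z_mm)$values
  }
  out
}

#' Loss of the plug-and-play objective
#'
#' Evaluates the three terms of the objective at the given variables:
#' data fidelity `1/2 ||H(R_theta(uo)) - I_tau||^2`, prior regularization
#' `(alpha/2) * Re<uo, uo - u_tau>`, and proximity
#' `(beta/2) * ||uo - R_theta(uo) - t||^2`.
#'
#' @param theta generator parameters.
#' @param uo complex object estimate (matrix).
#' @param t_mult complex multiplier field (matrix).
#' @param prior a [make_prior()] bundle.
#' @param config an [admm_config()].
#' @param pitch_um,wavelength_nm,z_mm geometry of the reconstruction grid.
#' @return List with `total`, `fidelity`, `prior`, `proximity` and the
#'   generator output `R_uo`.
#' @export
admm_loss <- function(theta, uo, t_mult, prior, config,
                      pitch_um, wavelength_nm, z_mm, net_in = uo) {
  R_uo <- generate(theta, net_in)
  fid <- fidelity_and_grad(R_uo, prior$I_tau$intensity, pitch_um,
                           wavelength_nm, z_mm, want_grad = FALSE)$value
  alpha <- if (prior$alpha_disabled) 0 else config$alpha
  pri <- 0.5 * alpha * Re(sum(Conj(uo) * (uo - prior$u_tau)))
  w <- uo - R_uo - t_mult
  prox <- 0.5 * config$beta * sum(Mod(w)^2)
  if (!is.finite(fid + pri + prox))
    stop("non-finite loss (fidelity = ", fid, ", prior = ", pri,
         ", proximity = ", prox, ")")
  list(total = fid + pri + prox, fidelity = fid, prior = pri,
       proximity = prox, R_uo = R_uo)
}

#' Update the generator parameters (theta step)
#'
#' Runs `inner_theta_steps` Adam steps on the theta sub-objective
#' `1/2 ||H(R_theta(uo)) - I_tau||^2 + (beta/2) ||uo - R_theta(uo) - t||^2`
#' with the object and multiplier frozen (the prior term does not involve
#' theta). If the inner objective blows up by more than 10x the learning
#' rate is halved once for the rest of the run; a second blow-up aborts.
#'
#' @param state an [initialize_admm()] state.
#' @param prior,config bundle and configuration.
#' @return Updated state with `sub_obj$L_theta` set.
#' @export
update_theta <- function(state, prior, config) {
  nr <- nrow(state$uo); nc <- ncol(state$uo)
  x2 <- c2ch(net_input_of(state, config))
  L_theta <- NA_real_
  first <- NA_real_
  for (s in seq_len(config$inner_theta_steps)) {
    fw <- unet_forward(state$theta, x2, nr, nc, keep_cache = TRUE)
    v <- ch2c(fw$y, nr, nc)
    fg <- fidelity_and_grad(v, prior$I_tau$intensity, state$pitch_um,
                            state$wavelength_nm, state$z_mm)
    w <- state$uo - v - state$t_mult
    L_theta <- fg$value + 0.5 * config$beta * sum(Mod(w)^2)
    if (is.na(first)) first <- L_theta
    if (!is.finite(L_theta) || L_theta > 10 * first + 1e-12) {
      if (state$lr_scale > 0.5) {
        state$lr_scale <- 0.5
      } else {
        stop("theta update diverged (inner objective grew > 10x)")
      }
    }
    g_conj <- fg$grad_conj - 0.5 * config$beta * w  # d/d conj(v)
    dy <- 2 * cbind(as.vector(Re(g_conj)), as.vector(Im(g_conj)))
    bw <- unet_backward(state$theta, fw, dy)
    up <- adam_step(state$theta, bw$grad, state$opt,
                    lr = config$theta_lr * state$lr_scale)
    state$theta <- up$theta
    state$opt <- up$state
  }
  if (config$inner_theta_steps == 0L) {
    # still report the current sub-objective for the stopping rule
    v <- generate(state$theta, net_input_of(state, config))
    fg <- fidelity_and_grad(v, prior$I_tau$intensity, state$pitch_um,
                            state$wavelength_nm, state$z_mm, want_grad = FALSE)
    L_theta <- fg$value +
      0.5 * config$beta * sum(Mod(state$uo - v - state$t_mult)^2)
  }
  state$sub_obj$L_theta <- L_theta
  state
}

#' Update the object estimate (steepest-descent step)
#'
#' Explicit gradient step on the prior and proximity terms with theta and
#' the multiplier frozen:
#' `uo <- uo - c * (alpha * (uo - u_tau) + beta * (uo - R_theta(uo) - t))`.
#'
#' @param state state whose `R_cache` holds `R_theta(uo^k)` (set by
#'   [run_admm_epoch()]); if absent it is computed.
#' @param prior,config bundle and configuration.
#' @return Updated state with `sub_obj$L_uo` set and `step_flagged` when the
#'   update norm exceeded the field norm.
#' @export
update_object <- function(state, prior, config) {
  R_uo <- state$R_cache
  if (is.null(R_uo)) R_uo <- generate(state$theta, net_input_of(state, state$config))
  alpha <- if (prior$alpha_disabled) 0 else config$alpha
  g <- alpha * (state$uo - prior$u_tau) +
    config$beta * (state$uo - R_uo - state$t_mult)
  step <- config$c_step * g
  if (sqrt(sum(Mod(step)^2)) > sqrt(sum(Mod(state$uo)^2)))
    state$step_flagged <- TRUE
  state$uo <- state$uo - step
  w <- state$uo - R_uo - state$t_mult
  state$sub_obj$L_uo <- 0.5 * alpha * Re(sum(Conj(state$uo) * (state$uo - prior$u_tau))) +
    0.5 * config$beta * sum(Mod(w)^2)
  state
}

#' Update the Lagrange multiplier
#'
#' Default (`"residual"`): `t <- t - (uo - R_theta(uo))`, the ascent step on
#' the splitting constraint, which leaves `t` unchanged exactly when the
#' constraint `uo = R_theta(uo)` holds. The `"sum"` variant replaces the
#' residual by `uo + R_theta(uo)`.
#'
#' @param state state (uses `R_cache`, the generator output at the previous
#'   object estimate).
#' @param config an [admm_config()].
#' @return Updated state with `sub_obj$L_t` set.
#' @export
update_multiplier <- function(state, config) {
  R_uo <- state$R_cache
  if (is.null(R_uo)) R_uo <- generate(state$theta, net_input_of(state, state$config))
  resid <- if (config$multiplier_sign == "residual") state$uo - R_uo
           else state$uo + R_uo
  state$t_mult <- state$t_mult - resid
  w <- state$uo - R_uo - state$t_mult
  state$sub_obj$L_t <- 0.5 * config$beta * sum(Mod(w)^2)
  state
}

#' Stagnation-based stopping rule
#'
#' Each epoch produces three sub-objective values (theta, object,
#' multiplier). The rule compares consecutive epochs through
#' `eps_i = |L_i^k - L_i^(k-1)| / n`, where `n` is the number of object
#' pixels, and stops when `max(eps_1, eps_2, eps_3) <= tol / 3`.
#'
#' @param eps numeric vector of the three residuals (already divided by `n`).
#' @param tol tolerance (default 1e-3).
#' @return Logical.
#' @export
check_convergence <- function(eps, tol = 1e-3) {
  stopifnot(length(eps) >= 1)
  all(is.finite(eps)) && max(eps) <= tol / 3
}

# One full sequential epoch: theta -> object -> multiplier.
run_admm_epoch <- function(state, prior, config) {
  state <- update_theta(state, prior, config)
  state$R_cache <- generate(state$theta, net_input_of(state, config))
  state <- update_object(state, prior, config)
  state <- update_multiplier(state, config)
  state$k <- state$k + 1L
  state
}

#' Plug-and-play reconstruction of a hologram
#'
#' Full pipeline: build the prior bundle, initialize, iterate the
#' theta/object/multiplier updates until the stagnation rule fires or the
#' epoch cap is reached, and return the unwrapped phase and amplitude of the
#' final object estimate at the upsampled resolution.
#'
#' Modes map onto prior bundles: `"dip"` (no prior pull), `"dip-red"`
#' (total-variation denoiser prior), `"hdphysnet"` (file prior when
#' `prior_phase` is given, otherwise the bicubic prior).
#'
#' @param holo a [hologram()].
#' @param mode `"dip"`, `"dip-red"` or `"hdphysnet"`.
#' @param config an [admm_config()].
#' @param gen_spec a [generator_spec()].
#' @param prior_phase optional prior phase image (radians, upsampled shape).
#' @param upsample_factor 1, 2 or 4.
#' @param z_mm known reconstruction distance (mm) or `"auto"`.
#' @param unwrap_method passed to [unwrap_phase()].
#' @return A list with `phase` (unwrapped, background-zeroed), `amplitude`,
#'   `field` (complex estimate), `prior`, and `diagnostics` (per-epoch loss
#'   terms, the three stagnation residuals, stop reason, epochs run, seed).
#' @export
reconstruct_pnp <- function(holo, mode = c("hdphysnet", "dip", "dip-red"),
                            config = admm_config(), gen_spec = generator_spec(),
                            prior_phase = NULL, upsample_factor = 1,
                            z_mm = "auto", unwrap_method = "quality") {
  mode <- match.arg(mode)
  prior_mode <- switch(mode,
                       dip = "none",
                       `dip-red` = "tv",
                       hdphysnet = if (is.null(prior_phase)) "bicubic" else "file")
  prior <- make_prior(holo, prior_mode, upsample_factor, prior_phase, z_mm)
  state <- initialize_admm(holo, prior, gen_spec, config)
  n_px <- length(state$uo)
  losses <- vector("list", config$max_epochs)
  eps_hist <- matrix(NA_real_, config$max_epochs, 3,
                     dimnames = list(NULL, c("eps1", "eps2", "eps3")))
  prev <- NULL
  under <- 0L
  stop_reason <- "max_epochs"
  for (k in seq_len(config$max_epochs)) {
    state <- run_admm_epoch(state, prior, config)
    # loss terms at the epoch's cached generator output (no extra forward)
    fid <- fidelity_and_grad(state$R_cache, prior$I_tau$intensity,
                             state$pitch_um, state$wavelength_nm,
                             state$z_mm, want_grad = FALSE)$value
    alpha_k <- if (prior$alpha_disabled) 0 else config$alpha
    pri <- 0.5 * alpha_k * Re(sum(Conj(state$uo) * (state$uo - prior$u_tau)))
    prox <- 0.5 * config$beta *
      sum(Mod(state$uo - state$R_cache - state$t_mult)^2)
    if (!is.finite(fid + pri + prox))
      stop("non-finite loss at epoch ", k, " (fidelity = ", fid,
           ", prior = ", pri, ", proximity = ", prox, ")")
    losses[[k]] <- c(total = fid + pri + prox, fidelity = fid,
                     prior = pri, proximity = prox)
    cur <- unlist(state$sub_obj[c("L_theta", "L_uo", "L_t")])
    if (!is.null(prev)) {
      eps <- abs(cur - prev) / n_px
      eps_hist[k, ] <- eps
      if (config$tol > 0 && check_convergence(eps, config$tol)) {
        under <- under + 1L
        if (under >= 5L) {
          stop_reason <- "tolerance"
          break
        }
      } else {
        under <- 0L
      }
    }
    prev <- cur
  }
  epochs_run <- state$k
  field <- complex_field(state$uo, state$pitch_um, state$wavelength_nm)
  ap <- extract_amp_phase(field, unwrap = TRUE, method = unwrap_method)
  loss_mat <- do.call(rbind, losses[seq_len(epochs_run)])
  list(
    phase = ap$phase, amplitude = ap$amplitude, field = field, prior = prior,
    diagnostics = list(
      loss = as.data.frame(loss_mat),
      eps = as.data.frame(eps_hist[seq_len(epochs_run), , drop = FALSE]),
      stop_reason = stop_reason, epochs_run = epochs_run,
      seed = config$seed, z_mm = state$z_mm, mode = mode,
      prior_mode = prior$mode, step_flagged = isTRUE(state$step_flagged)
    )
  )
}
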