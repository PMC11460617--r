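# Plug-and-play ADMM core: prior bundles, initialization, the loss and its
# three updates against scalar/closed-form oracles, and the stopping rule.

make_test_holo <- function(n = 64, peak = 1.5, z = 1, seed = 2) {
  obj <- make_cell_phantom(n, peak_phase_rad = peak, seed = seed)
  forward_hologram(object_field(obj),
                   optical_config(z2_mm = z, sensor_shape = c(n, n)))
}

test_that("prior bundles honour their mode contracts", {
  h <- make_test_holo()
  p0 <- make_prior(h, "none", 1, z_mm = 1)
  expect_true(p0$alpha_disabled)
  expect_true(all(p0$phi_tau == 0))
  expect_equal(dim(p0$I_tau$intensity), c(64L, 64L))
  # upsampling doubles the grid and halves the pitch
  p2 <- make_prior(h, "bicubic", 2, z_mm = 1)
  expect_equal(dim(p2$I_tau$intensity), c(128L, 128L))
  expect_equal(p2$I_tau$pitch_um, h$pitch_um / 2)
  expect_equal(dim(p2$u_tau), c(128L, 128L))
  # the trained object has constant modulus by construction
  expect_lt(diff(range(Mod(p2$u_tau))), 1e-12)
  # file mode validates the shape
  expect_error(make_prior(h, "file", 2, prior_phase = matrix(0, 64, 64),
                          z_mm = 1), "shape")
  pf <- make_prior(h, "file", 1, prior_phase = matrix(0.3, 64, 64), z_mm = 1)
  expect_equal(pf$phi_tau, matrix(0.3, 64, 64))
})

test_that("initialization starts from the backprojection with zero multiplier", {
  h <- make_test_holo()
  prior <- make_prior(h, "bicubic", 1, z_mm = 1)
  cfg <- admm_config(seed = 5)
  st <- initialize_admm(h, prior, generator_spec(), cfg)
  expect_true(all(st$t_mult == 0 + 0i))
  expect_identical(st$k, 0L)
  expect_equal(st$uo, backpropagate(prior$I_tau, 1)$values)
  # same seed reproduces the initial loss exactly
  st2 <- initialize_admm(h, prior, generator_spec(), cfg)
  l1 <- admm_loss(st$theta, st$uo, st$t_mult, prior, cfg, st$pitch_um,
                  st$wavelength_nm, st$z_mm)
  l2 <- admm_loss(st2$theta, st2$uo, st2$t_mult, prior, cfg, st2$pitch_um,
                  st2$wavelength_nm, st2$z_mm)
  expect_identical(l1$total, l2$total)
})

test_that("loss terms match a first-principles evaluation", {
  h <- make_test_holo(n = 16)
  prior <- make_prior(h, "bicubic", 1, z_mm = 1)
  cfg <- admm_config(alpha = 0.7, beta = 0.4, seed = 3)
  st <- initialize_admm(h, prior, generator_spec(depth = 2, base_channels = 3,
                                                 skip_channels = 2), cfg)
  set.seed(9)
  tm <- matrix(complex(real = rnorm(256, 0, 0.1)), 16, 16)
  lt <- admm_loss(st$theta, st$uo, tm, prior, cfg, st$pitch_um,
                  st$wavelength_nm, st$z_mm)
  # recompute every term with plain complex arithmetic
  v <- generate(st$theta, st$uo)
  V <- angular_spectrum_propagate(complex_field(v, st$pitch_um, 627), 1)$values
  fid <- 0.5 * sum((Mod(V)^2 - prior$I_tau$intensity)^2)
  pri <- 0.5 * 0.7 * Re(sum(Conj(st$uo) * (st$uo - prior$u_tau)))
  prox <- 0.5 * 0.4 * sum(Mod(st$uo - v - tm)^2)
  expect_equal(lt$fidelity, fid, tolerance = 1e-12)
  expect_equal(lt$prior, pri, tolerance = 1e-12)
  expect_equal(lt$proximity, prox, tolerance = 1e-12)
  expect_equal(lt$total, fid + pri + prox, tolerance = 1e-12)
})

test_that("with alpha = beta = 0 the loss reduces to the physics fidelity", {
  h <- make_test_holo(n = 16)
  prior <- make_prior(h, "none", 1, z_mm = 1)
  cfg <- admm_config(alpha = 0, beta = 0, c_step = 1, seed = 3)
  st <- initialize_admm(h, prior, generator_spec(depth = 2, base_channels = 3,
                                                 skip_channels = 2), cfg)
  lt <- admm_loss(st$theta, st$uo, st$t_mult, prior, cfg, st$pitch_um,
                  st$wavelength_nm, st$z_mm)
  expect_identical(lt$total, lt$fidelity)
  expect_identical(lt$prior, 0)
  expect_identical(lt$proximity, 0)
})

test_that("zero inner steps leave the generator untouched", {
  h <- make_test_holo(n = 32)
  prior <- make_prior(h, "bicubic", 1, z_mm = 1)
  cfg <- admm_config(inner_theta_steps = 0, seed = 3)
  st <- initialize_admm(h, prior, generator_spec(depth = 2, base_channels = 3,
                                                 skip_channels = 2), cfg)
  before <- holopnp:::flatten_theta(st$theta)
  st2 <- update_theta(st, prior, cfg)
  expect_identical(holopnp:::flatten_theta(st2$theta), before)
  expect_true(is.finite(st2$sub_obj$L_theta))
})

test_that("object update follows its closed-form geometric recursion", {
  # beta = 0: uo^{m} - u_tau = (1 - c*alpha)^m (uo^0 - u_tau), exactly
  h <- make_test_holo(n = 16)
  prior <- make_prior(h, "bicubic", 1, z_mm = 1)
  cfg <- admm_config(alpha = 0.4, beta = 0, c_step = 0.3, seed = 1)
  st <- initialize_admm(h, prior, generator_spec(depth = 2, base_channels = 3,
                                                 skip_channels = 2), cfg)
  st$R_cache <- st$uo  # unused at beta = 0 but must be present
  uo0 <- st$uo
  for (m in 1:25) st <- update_object(st, prior, cfg)
  expected <- prior$u_tau + (1 - 0.3 * 0.4)^25 * (uo0 - prior$u_tau)
  expect_lt(max(Mod(st$uo - expected)), 1e-10)
  # and with alpha = beta = 0 the object never moves
  cfg0 <- admm_config(alpha = 0, beta = 0, c_step = 1, seed = 1)
  st0 <- initialize_admm(h, prior, generator_spec(depth = 2, base_channels = 3,
                                                  skip_channels = 2), cfg0)
  st0$R_cache <- st0$uo
  st0b <- update_object(st0, prior, cfg0)
  expect_identical(st0b$uo, st0$uo)
})

test_that("the update fixed point is stationary", {
  h <- make_test_holo(n = 16)
  prior <- make_prior(h, "bicubic", 1, z_mm = 1)
  cfg <- admm_config(alpha = 0.5, beta = 0.5, seed = 1)
  st <- initialize_admm(h, prior, generator_spec(depth = 2, base_channels = 3,
                                                 skip_channels = 2), cfg)
  # engineer uo = u_tau and R + t = uo: both gradients vanish
  st$uo <- prior$u_tau
  st$R_cache <- prior$u_tau * 0.6
  st$t_mult <- prior$u_tau * 0.4
  st2 <- update_object(st, prior, cfg)
  expect_lt(max(Mod(st2$uo - st$uo)), 1e-12)
})

test_that("multiplier update subtracts the splitting residual", {
  h <- make_test_holo(n = 16)
  prior <- make_prior(h, "bicubic", 1, z_mm = 1)
  cfg <- admm_config(seed = 1)
  st <- initialize_admm(h, prior, generator_spec(depth = 2, base_channels = 3,
                                                 skip_channels = 2), cfg)
  # zero residual: t unchanged
  st$R_cache <- st$uo
  st2 <- update_multiplier(st, cfg)
  expect_identical(st2$t_mult, st$t_mult)
  # two hand-iterated scalar updates match the implementation exactly
  uo <- matrix(0.8 + 0.1i, 16, 16)
  R1 <- matrix(0.6 + 0.0i, 16, 16)
  st$uo <- uo; st$R_cache <- R1; st$t_mult <- matrix(0 + 0i, 16, 16)
  s1 <- update_multiplier(st, cfg)
  expect_equal(s1$t_mult, -(uo - R1), tolerance = 1e-15)
  R2 <- matrix(0.7 + 0.05i, 16, 16)
  s1$R_cache <- R2
  s2 <- update_multiplier(s1, cfg)
  expect_equal(s2$t_mult, -(uo - R1) - (uo - R2), tolerance = 1e-15)
  # the literal printed form uses the sum instead of the residual
  cfg_sum <- admm_config(multiplier_sign = "sum", seed = 1)
  st$R_cache <- R1; st$t_mult <- matrix(0 + 0i, 16, 16)
  s3 <- update_multiplier(st, cfg_sum)
  expect_equal(s3$t_mult, -(uo + R1), tolerance = 1e-15)
})

test_that("theta sub-objective gradient matches central differences end to end", {
  set.seed(3)
  n <- 16; pitch <- 1.67; wl <- 627; z <- 1; beta <- 0.5
  I <- matrix(runif(n * n, 0.5, 1.5), n)
  uo <- matrix(complex(real = rnorm(n * n, 1, 0.2),
                       imaginary = rnorm(n * n, 0, 0.2)), n)
  tm <- matrix(complex(real = rnorm(n * n, 0, 0.05),
                       imaginary = rnorm(n * n, 0, 0.05)), n)
  th <- init_generator(generator_spec(depth = 2, base_channels = 3,
                                      skip_channels = 2, seed = 2))
  obj_at <- function(vec) {
    t2 <- holopnp:::relist_theta(vec, th)
    v <- generate(t2, uo)
    holopnp:::fidelity_and_grad(v, I, pitch, wl, z, want_grad = FALSE)$value +
      0.5 * beta * sum(Mod(uo - v - tm)^2)
  }
  x2 <- holopnp:::c2ch(uo)
  fw <- holopnp:::unet_forward(th, x2, n, n, keep_cache = TRUE)
  v <- holopnp:::ch2c(fw$y, n, n)
  fg <- holopnp:::fidelity_and_grad(v, I, pitch, wl, z)
  g_conj <- fg$grad_conj - 0.5 * beta * (uo - v - tm)
  dy <- 2 * cbind(as.vector(Re(g_conj)), as.vector(Im(g_conj)))
  bw <- holopnp:::unet_backward(th, fw, dy)
  g <- rapply(bw$grad, identity, how = "unlist")
  lv <- holopnp:::flatten_theta(th)
  set.seed(9)
  probes <- sample(length(lv), 8)
  eps <- 1e-6
  num <- vapply(probes, function(i) {
    v1 <- lv; v1[i] <- v1[i] + eps
    v2 <- lv; v2[i] <- v2[i] - eps
    (obj_at(v1) - obj_at(v2)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(num - g[probes]) / (abs(num) + 1e-6)), 1e-3)
})

test_that("the stopping rule applies the printed arithmetic", {
  expect_true(check_convergence(c(1e-4, 2e-4, 3e-4), tol = 1e-3))
  expect_false(check_convergence(c(1e-3, 0, 0), tol = 1e-3))
  expect_false(check_convergence(c(NA, 0, 0), tol = 1e-3))
})

test_that("a short run is deterministic and monotone in its theta objective", {
  h <- make_test_holo(n = 48, peak = 1)
  cfg <- admm_config(tol = 0, max_epochs = 12, seed = 4)
  r1 <- reconstruct_pnp(h, "hdphysnet", cfg, generator_spec(depth = 2,
                                                            base_channels = 4,
                                                            skip_channels = 2),
                        z_mm = 1)
  r2 <- reconstruct_pnp(h, "hdphysnet", cfg, generator_spec(depth = 2,
                                                            base_channels = 4,
                                                            skip_channels = 2),
                        z_mm = 1)
  expect_identical(r1$phase, r2$phase)
  expect_identical(r1$diagnostics$loss, r2$diagnostics$loss)
  expect_equal(r1$diagnostics$epochs_run, 12)
  expect_equal(r1$diagnostics$stop_reason, "max_epochs")
  drops <- diff(r1$diagnostics$loss$fidelity)
  expect_gt(mean(drops <= 0), 0.7)
  expect_true(all(c("eps1", "eps2", "eps3") %in% names(r1$diagnostics$eps)))
})
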