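zero_coupling_config <- function(seed = 11) {
  model_config(N = 2, M = 2, K_GO = 0, K_MO = 0, eps_G = 0, eps_O = 0,
               F_GO = 0, F_MO = 0, seed = seed)
}

test_that("both integrators reproduce the free-oscillator closed form", {
  cfg <- zero_coupling_config()
  for (integ in c("adaptive", "rk4")) {
    sp <- simulation_spec(t_total = 1000, t_transient = 0,
                          sample_interval = 0.5, integrator = integ,
                          rk4_step = 0.05)
    ps <- integrate_model(cfg, sp)
    for (el in c("G", "GO", "O", "MO")) {
      th <- ps[[paste0("theta_", el)]]
      p <- cfg[[paste0("freq_", el)]]
      for (j in seq_len(ncol(th))) {
        ref <- free_phase(p, ps$offsets[[el]][j], th[1, j], ps$times)
        expect_lt(max(abs(th[, j] - ref)), 1e-5)
      }
    }
  }
})

test_that("constant-frequency runs are exactly linear in time", {
  cfg <- model_config(N = 2, M = 1, K_GO = 0, K_MO = 0, eps_G = 0,
                      eps_O = 0, freq_G = frequency_params(0.11),
                      freq_O = frequency_params(0.22),
                      freq_GO = frequency_params(0.33),
                      freq_MO = frequency_params(0.44), seed = 2)
  ps <- integrate_model(cfg, simulation_spec(t_total = 1000, t_transient = 0,
                                             sample_interval = 1))
  expect_lt(max(abs(ps$theta_GO[, 1] -
                    (ps$theta_GO[1, 1] + 0.33 * ps$times))), 1e-8)
  expect_lt(max(abs(ps$theta_O[, 1] -
                    (ps$theta_O[1, 1] + 0.22 * ps$times))), 1e-8)
})

test_that("fixed-step RK4 shows fourth-order convergence", {
  cfg <- model_config(N = 1, M = 1, K_GO = 0, K_MO = 0, eps_G = 0,
                      eps_O = 0,
                      freq_G = frequency_params(1, 0.8, 0.5),
                      freq_O = frequency_params(1, 0.8, 0.5),
                      freq_GO = frequency_params(1, 0.8, 0.5),
                      freq_MO = frequency_params(1, 0.8, 0.5), seed = 3)
  err_at <- function(h) {
    sp <- simulation_spec(t_total = 50, t_transient = 0,
                          sample_interval = 2.5, integrator = "rk4",
                          rk4_step = h)
    ps <- integrate_model(cfg, sp)
    ref <- free_phase(cfg$freq_GO, ps$offsets$GO[1], ps$theta_GO[1, 1],
                      ps$times)
    max(abs(ps$theta_GO[, 1] - ref))
  }
  e1 <- err_at(0.5)
  e2 <- err_at(0.25)
  e3 <- err_at(0.125)
  expect_gt(e2, 1e-12)  # above round-off, so the ratios are meaningful
  expect_gt(e1 / e2, 12)
  expect_lt(e1 / e2, 20)
  expect_gt(e2 / e3, 12)
  expect_lt(e2 / e3, 20)
})

test_that("adaptive and fixed-step trajectories agree on a coupled run", {
  cfg <- model_config(N = 3, M = 3, F_GO = 0.1, F_MO = 0.1, seed = 4)
  sp_a <- simulation_spec(t_total = 1000, t_transient = 0,
                          sample_interval = 0.5)
  sp_r <- simulation_spec(t_total = 1000, t_transient = 0,
                          sample_interval = 0.5, integrator = "rk4")
  pa <- integrate_model(cfg, sp_a)
  pb <- integrate_model(cfg, sp_r)
  expect_lt(max(abs(pa$theta_GO - pb$theta_GO),
                abs(pa$theta_MO - pb$theta_MO),
                abs(pa$theta_G - pb$theta_G)), 1e-3)
})

test_that("tightening adaptive tolerances changes phases less than the looser tolerance", {
  cfg <- model_config(N = 3, M = 3, F_GO = 0.15, F_MO = 0.05, seed = 9)
  run <- function(rt, at) {
    integrate_model(cfg, simulation_spec(t_total = 500, t_transient = 0,
                                         sample_interval = 0.5,
                                         rel_tol = rt, abs_tol = at))
  }
  loose <- run(1e-6, 1e-8)
  tight <- run(1e-8, 1e-10)
  dmax <- max(abs(loose$theta_GO - tight$theta_GO),
              abs(loose$theta_MO - tight$theta_MO))
  # per-step error is tolerance-controlled; the global difference may
  # accumulate over the few hundred steps of the run, hence the O(10) factor
  expect_lt(dmax, 10 * 1e-6 * max(abs(tight$theta_GO)))
})

test_that("trajectories are deterministic given the seeds", {
  cfg <- small_config(seed = 21)
  sp <- simulation_spec(t_total = 200, t_transient = 0, sample_interval = 1)
  a <- integrate_model(cfg, sp)
  b <- integrate_model(cfg, sp)
  expect_identical(a$theta_GO, b$theta_GO)
  expect_identical(a$offsets, b$offsets)
  # a different config seed changes offsets and initial phases
  cfg2 <- small_config(seed = 22)
  c2 <- integrate_model(cfg2, sp)
  expect_false(identical(a$theta_GO[1, ], c2$theta_GO[1, ]))
})

test_that("frequency noise runs under rk4 only and is seed-deterministic", {
  cfg <- model_config(N = 2, M = 2, noise_sigma = 0.05, seed = 5)
  expect_error(integrate_model(cfg, simulation_spec(t_total = 10,
                                                    t_transient = 0)),
               "rk4")
  sp <- simulation_spec(t_total = 50, t_transient = 0, sample_interval = 0.5,
                        integrator = "rk4", rk4_step = 0.05, seed = 77)
  a <- integrate_model(cfg, sp)
  b <- integrate_model(cfg, sp)
  expect_identical(a$theta_GO, b$theta_GO)
  sp2 <- simulation_spec(t_total = 50, t_transient = 0,
                         sample_interval = 0.5, integrator = "rk4",
                         rk4_step = 0.05, seed = 78)
  c2 <- integrate_model(cfg, sp2)
  expect_false(identical(a$theta_GO, c2$theta_GO))
  # noise only perturbs the network oscillators, not the drivers
  expect_identical(a$theta_G, c2$theta_G)
})

test_that("discard_transient keeps the grid and the tail window", {
  cfg <- small_config(seed = 6)
  ps <- integrate_model(cfg, simulation_spec(t_total = 100, t_transient = 0,
                                             sample_interval = 0.5))
  full <- discard_transient(ps, 0)
  expect_identical(full$times, ps$times)
  cut <- discard_transient(ps, 50)
  expect_equal(cut$times[1], 50)
  expect_equal(diff(cut$times)[1], 0.5)
  expect_equal(nrow(cut$theta_GO), length(cut$times))
  expect_error(discard_transient(ps, 100.5), "empty")
})

test_that("schedule-valued couplings match the equivalent scalar run", {
  base <- model_config(N = 2, M = 2, F_GO = 0.12, F_MO = 0.08, seed = 8)
  sched <- model_config(N = 2, M = 2,
                        F_GO = constant_schedule(0.12, 500),
                        F_MO = constant_schedule(0.08, 500), seed = 8)
  sp <- simulation_spec(t_total = 400, t_transient = 0, sample_interval = 1)
  a <- integrate_model(base, sp)
  b <- integrate_model(sched, sp)
  expect_lt(max(abs(a$theta_GO - b$theta_GO),
                abs(a$theta_MO - b$theta_MO)), 1e-10)
})

test_that("negative schedule evaluations clamp to zero with a warning", {
  ramp <- schedule(data.frame(t_start = 0, t_end = 100, a = 0, b = -0.01,
                              c = 0.2))  # crosses zero at t = 20
  cfg <- model_config(N = 1, M = 1, eps_G = ramp, seed = 10)
  sp <- simulation_spec(t_total = 100, t_transient = 0, sample_interval = 1)
  expect_warning(integrate_model(cfg, sp), "clamped")
  expect_equal(schedule_value(ramp, c(0, 20, 50)), c(0.2, 0, 0))
  expect_equal(schedule_value(ramp, 50, clamp = FALSE), -0.3)
})

test_that("phase series round-trips through disk", {
  cfg <- small_config(N = 2, M = 3, seed = 12)
  ps <- integrate_model(cfg, simulation_spec(t_total = 20, t_transient = 0,
                                             sample_interval = 1))
  dir <- withr::local_tempdir()
  write_phase_series(ps, dir)
  back <- read_phase_series(dir)
  expect_equal(back$times, ps$times)
  expect_equal(unname(back$theta_GO), unname(ps$theta_GO), tolerance = 1e-12)
  expect_equal(back$offsets$MO, ps$offsets$MO, tolerance = 1e-12)
  expect_equal(back$config$F_GO, ps$config$F_GO)
  expect_equal(back$config$kernel$kind, ps$config$kernel$kind)
})

test_that("model config serialises to JSON and back, schedules included", {
  sch <- hela_schedules(hela_spec())
  cfg <- model_config(N = 7, M = 5, eps_G = sch$eps_G, F_GO = sch$F_GO,
                      F_MO = sch$F_MO, noise_sigma = 0.1, seed = 33,
                      kernel = weight_kernel("power_decay", 0.9),
                      mo_go_sign = "repulsive", offset_mode = "phase")
  path <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$N, 7L)
  expect_equal(back$kernel$kind, "power_decay")
  expect_equal(back$kernel$base, 0.9)
  expect_equal(back$mo_go_sign, "repulsive")
  expect_equal(back$offset_mode, "phase")
  expect_equal(schedule_value(back$eps_G, c(0, 100, 400)),
               schedule_value(cfg$eps_G, c(0, 100, 400)))
  expect_equal(schedule_value(back$F_GO, c(50, 383, 700)),
               schedule_value(cfg$F_GO, c(50, 383, 700)))
  expect_equal(back$freq_MO$omega_mean, cfg$freq_MO$omega_mean)
})

test_that("tidy and glance summarise a phase series", {
  cfg <- small_config(N = 2, M = 2, seed = 13)
  ps <- integrate_model(cfg, simulation_spec(t_total = 10, t_transient = 0,
                                             sample_interval = 1))
  td <- tidy(ps)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 11 * 8)
  expect_setequal(unique(td$element), c("G", "GO", "O", "MO"))
  gl <- glance(ps)
  expect_equal(gl$N, 2L)
  expect_equal(gl$n_samples, 11L)
})
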