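test_that("INa variants map presets onto gate shift and conductance scale", {
  a <- make_ina_variant("adult")
  expect_equal(a$act_shift, 0)
  expect_equal(a$g_scale, 1.0)
  f <- make_ina_variant("fetal")
  expect_equal(f$act_shift, 7)
  expect_equal(f$g_scale, 0.55)
  m <- make_ina_variant("mix")
  expect_equal(m$act_shift, 3.8)
  expect_equal(m$g_scale, 0.70)
  expect_error(make_ina_variant("embryonic"), "arg")
})

test_that("single cells rest stably and fire only when stimulated", {
  # no stimulus: after the initial-condition transient settles, the membrane
  # drifts by less than 1 mV over the remainder of a 5 s run
  for (ct in c("Endo", "M", "Epi")) {
    r <- run_cell(ct, stim_amplitude = 0, cycle_length = 5000, n_beats = 1,
                  gna_multiplier = 2)
    expect_false(r$activated)
    expect_lt(diff(range(r$v[r$time > 500])), 1)
  }
  r <- run_cell("Endo", stim_amplitude = 40, gna_multiplier = 2, n_beats = 2)
  expect_true(r$activated)
  expect_gt(r$dvdt_max, 100)
  expect_lt(r$v_rest, -85)
  expect_gt(r$apd90, 100)
})

test_that("upstroke velocity decreases monotonically with the Na conductance", {
  dvdt <- vapply(c(1.0, 0.7, 0.55, 0.35), function(g) {
    v <- structure(list(act_shift = 0, g_scale = g, source = "sweep"),
                   class = "ina_variant")
    run_cell("Endo", v, gna_multiplier = 2, n_beats = 2,
             stim_amplitude = 40)$dvdt_max
  }, numeric(1))
  expect_true(all(diff(dvdt) < 0))
  # fetal variant is less excitable than adult
  f <- run_cell("Endo", make_ina_variant("fetal"), gna_multiplier = 2,
                n_beats = 2, stim_amplitude = 40)
  a <- run_cell("Endo", make_ina_variant("adult"), gna_multiplier = 2,
                n_beats = 2, stim_amplitude = 40)
  expect_lt(f$dvdt_max, a$dvdt_max)
})

test_that("pseudo-ECG nulls, signs and QRS measurement behave as constructed", {
  tt <- seq(0, 100, 0.5)
  x <- seq(0, 1, 0.01)
  # spatially uniform field (any time course): identically zero trace
  vu <- matrix(rep(-85 + 100 * sin(tt / 30), length(x)), nrow = length(tt))
  flat <- pseudo_ecg(list(v = vu, time = tt, x = x), electrode_distance = 2.6)
  expect_true(all(abs(flat$phi) < 1e-9))
  expect_error(measure_qrs(flat), "flat")
  # rightward-travelling monotone front: strictly positive deflection that
  # grows as the front nears the electrode, vanishing once activation is
  # complete (negative phases need opposite-sign gradients, e.g.
  # repolarisation)
  front <- 0.02 * tt  # cm, reaches the end at t = 50
  vs <- outer(front, x, function(f, xx) ifelse(xx < f, 20, -85))
  step <- pseudo_ecg(list(v = vs, time = tt, x = x), electrode_distance = 2.6)
  mid <- tt > 5 & tt < 45
  expect_gt(min(step$phi[mid]), 0)
  expect_gt(step$phi[tt == 45], step$phi[tt == 10])
  expect_true(all(abs(step$phi[tt > 52]) < 1e-9))
  expect_error(pseudo_ecg(list(v = vs, time = tt, x = x),
                          electrode_distance = -1), "outside")
  # synthetic boxcar deflection of known 40 ms width
  phi <- numeric(length(tt)); phi[tt >= 20 & tt <= 60] <- 1
  q <- measure_qrs(structure(list(time = tt, phi = phi), class = "pseudo_ecg"))
  expect_equal(q$qrs_duration, 40, tolerance = 0.5 + 1e-9)
})

test_that("a decoupled or unstimulated cable stays put; blocks are reported", {
  w <- wedge_config(layer_thicknesses = c(Endo = 0.03, M = 0.06, Epi = 0.03),
                    n_beats = 2)
  # no stimulus: spatially uniform field throughout
  out <- cardiosplice:::wedge_run_raw(w, make_ina_variant("adult"),
                                      diffusion = 7e-5, stim_amplitude = 0,
                                      total_ms = 100, record_start_ms = 0)
  # layers differ only in IKr, whose gate is all but closed at rest, so the
  # field stays spatially uniform to well under a microvolt-scale gradient
  expect_lt(max(apply(out$v, 1, function(row) diff(range(row)))), 1e-3)
  # zero diffusion: no propagation beyond the stimulated region
  out0 <- cardiosplice:::wedge_run_raw(w, make_ina_variant("adult"),
                                       diffusion = 0, stim_amplitude = 60,
                                       total_ms = 100, record_start_ms = 99)
  expect_true(all(out0$n_activations[1:w$n_stim_nodes] >= 1))
  expect_true(all(out0$n_activations[(w$n_stim_nodes + 2):12] == 0))
  # a sub-threshold stimulus is reported as conduction block, not truncated
  expect_error(run_wedge(w, make_ina_variant("adult"), diffusion = 7e-5,
                         stim_amplitude = 1), "conduction block")
})

test_that("AH interval lengthens monotonically across the splice variants", {
  ah <- vapply(c("adult", "mix", "fetal"), function(vn)
    run_av_strand(vn)$ah_interval, numeric(1))
  expect_true(all(diff(ah) > 0))
  expect_gte(ah["fetal"] / ah["adult"], 1.4)
  # a crippled nodal segment reports conduction failure with the beat pattern
  weak <- av_config(nodal_gna = 2, n_nodal = 30, n_beats = 2)
  expect_warning(r <- run_av_strand("adult", weak), "conduction failure")
  expect_false(r$conducted)
  expect_true(is.na(r$ah_interval))
})
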