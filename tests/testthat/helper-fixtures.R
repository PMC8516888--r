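# memoised fixtures shared across test files: expensive field solves and the
# default rendered experiment are computed once per test run

.fixtures <- new.env(parent = emptyenv())

# reference field at 1500 V on the default 60 x 60 mm grid, h = 0.1 mm
ref_field <- function() {
  if (is.null(.fixtures$fm)) {
    pf <- solve_laplace(electrode_config(applied_voltage_V0 = 1500),
                        grid_spec())
    .fixtures$pf <- pf
    .fixtures$fm <- field_magnitude(pf)
  }
  .fixtures$fm
}

ref_potential <- function() {
  ref_field()
  .fixtures$pf
}

ref_zones <- function(v = 1500) {
  predict_zones(scale_field_map(ref_field(), v))
}

# fine-grid field at 1000 V, h = 0.05 mm (shared by the solver-oracle and
# grid-convergence checks)
fine_field <- function() {
  if (is.null(.fixtures$fm_fine)) {
    pf <- solve_laplace(electrode_config(applied_voltage_V0 = 1000),
                        grid_spec(spacing_h = 0.05))
    .fixtures$pf_fine <- pf
    .fixtures$fm_fine <- field_magnitude(pf)
  }
  .fixtures$fm_fine
}

fine_potential <- function() {
  fine_field()
  .fixtures$pf_fine
}

# default rendered 30-bundle experiment (5 voltages x 2 modalities x 3 reps)
default_experiment <- function() {
  if (is.null(.fixtures$exp)) {
    .fixtures$exp <- generate_experiment(master_seed = 1L,
                                         field_ref = ref_field())
  }
  .fixtures$exp
}

# segmentation of every bundle in the default experiment, with truth pairs
default_segmentation <- function() {
  if (is.null(.fixtures$seg)) {
    exp <- default_experiment()
    rows <- lapply(names(exp$bundles), function(id) {
      b <- exp$bundles[[id]]
      calib <- calibrate_scale(b$image)
      if (b$condition$modality == "ttc") {
        seg <- segment_ttc(b$image, calib)
        data.frame(id = id,
                   class = c("white", "red"),
                   truth = c(b$truth_areas[["ire"]], b$truth_areas[["re"]]),
                   measured = c(seg$areas[["white"]], seg$areas[["red"]]))
      } else {
        seg <- segment_melanin(b$image, calib)
        data.frame(id = id, class = "melanin",
                   truth = b$truth_areas[["melanin"]],
                   measured = seg$areas[["melanin"]])
      }
    })
    .fixtures$seg <- do.call(rbind, rows)
  }
  .fixtures$seg
}

# first-principles statistics oracles, independent of the stats module
pearson_bf <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); syy <- sum(y * y); sxy <- sum(x * y)
  r <- (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

paired_ttest_bf <- function(x, y) {
  d <- x - y
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1))
}
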