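test_that("checkpoints round-trip bit-exactly", {
  net <- tiny_dense_net(mode = "urfb", seed = 19)
  ds <- linearly_separable_dataset(8, 3, margin = 2, n = 30, seed = 19)
  net <- one_step(net, ds$x, ds$y)
  p <- tempfile(fileext = ".rds")
  save_checkpoint(net, p)
  back <- load_checkpoint(p)
  expect_identical(all_W(back), all_W(net))
  expect_identical(all_R(back), all_R(net))
  expect_identical(back$spec$text, net$spec$text)
  unlink(p)
})

test_that("run_experiment trains, writes artifacts, and reruns identically", {
  out1 <- tempfile(); out2 <- tempfile()
  cfg <- list(task = "train",
              arch = "Conv 4 3x3; Maxpool 3; Full 16; Output",
              mode = "urfb", epochs = 2, batch_size = 30, seed = 5,
              data = list(n_per_class = 30L), out = out1)
  run_experiment(cfg)
  expect_true(file.exists(file.path(out1, "metrics.csv")))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  expect_true(file.exists(file.path(out1, "checkpoint.rds")))
  m <- read.csv(file.path(out1, "metrics.csv"))
  expect_equal(nrow(m), 2)
  expect_true(all(m$train_error >= 0 & m$train_error <= 1))
  # manifest holds the resolved config and seed
  man <- jsonlite::read_json(file.path(out1, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$seed, 5)
  expect_equal(man$config$arch, cfg$arch)
  # bitwise reproducible metrics from the same config
  cfg$out <- out2
  run_experiment(cfg)
  expect_identical(readBin(file.path(out1, "metrics.csv"), "raw", 1e6),
                   readBin(file.path(out2, "metrics.csv"), "raw", 1e6))
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("run_experiment rejects unknown tasks; config files round-trip", {
  expect_error(run_experiment(list(task = "frobnicate")), "usage error")
  p <- tempfile(fileext = ".yaml")
  writeLines(c("task: train", "arch: 'Full 8; Output'", "epochs: 1",
               "batch_size: 20", "seed: 3", "mode: frfb",
               "data:", "  n_per_class: 10"), p)
  cfg <- read_run_config(p)
  expect_equal(cfg$mode, "frfb")
  expect_equal(cfg$data$n_per_class, 10)
  expect_equal(cfg$lr, 0.1)          # defaults merged in
  unlink(p)
})

test_that("compare_modes shares epoch-0 behavior across modes via seeds", {
  cfg <- list(task = "train", arch = "Full 12; Output", epochs = 2,
              batch_size = 50, seed = 8,
              data = list(n_per_class = 40L))
  cm <- compare_modes(cfg, modes = c("bp", "urfb"))
  expect_named(cm$fits, c("bp", "urfb"))
  expect_true(all(c("bp_val_error", "urfb_val_error") %in% names(cm$report)))
  # same seed => identical initial feedforward weights
  expect_identical(all_W(build_network(cm$fits$bp$network$spec, seed = 8)),
                   all_W(build_network(cm$fits$urfb$network$spec, seed = 8)))
  expect_equal(nrow(cm$report), 2)
})

test_that("CLI flag parsing and usage errors", {
  fl <- hebbnet:::parse_cli_flags(c("--mode", "frfb", "--epochs", "3",
                                    "--untied", "--lr", "0.05"))
  expect_equal(fl$mode, "frfb")
  expect_equal(fl$epochs, 3L)
  expect_true(fl$untied)
  expect_equal(fl$lr, 0.05)
  expect_error(hebbnet:::parse_cli_flags(c("--bogus", "1")), "usage error")
  expect_error(hebbnet:::parse_cli_flags(c("--lr")), "usage error")
})

test_that("simulate-linear task produces the sweep frame", {
  res <- run_experiment(list(task = "simulate-linear", seed = 2,
                             dims = c(6, 8, 4), steps = 30, dt = 0.01,
                             epsilons = c(0, 1)))
  expect_true(all(c("eps_0", "eps_1", "bp") %in% names(res$traces)))
  expect_s3_class(res$frame, "data.frame")
})
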