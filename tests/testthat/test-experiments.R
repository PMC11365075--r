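# Scripted experiment surface: file layouts, manifests, reproducibility of
# command outputs, and agreement between the evaluation command and the
# metric functions it wraps.

small_cfg <- function(dir, ...) {
  c(list(output_dir = dir, n_train = 3L, n_test = 2L, seed = 4L,
         params = list(image_size = 32L)), list(...))
}

test_that("phantom command writes the dataset, manifest, and reproduces", {
  root <- withr::local_tempdir()
  d1 <- file.path(root, "a"); d2 <- file.path(root, "b")
  run_phantom(small_cfg(d1))
  expect_length(list.files(file.path(d1, "train", "images")), 3)
  expect_length(list.files(file.path(d1, "test", "masks")), 2)
  expect_true(file.exists(file.path(d1, "manifest.yaml")))
  man <- yaml::read_yaml(file.path(d1, "manifest.yaml"))
  expect_equal(man$seed, 4)
  expect_equal(man$params$image_size, 32)

  run_phantom(small_cfg(d2))
  f1 <- file.path(d1, "train", "images", "train_0001.png")
  f2 <- file.path(d2, "train", "images", "train_0001.png")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("train command writes checkpoint, loss log and manifest", {
  root <- withr::local_tempdir()
  data_dir <- file.path(root, "data")
  run_phantom(small_cfg(data_dir))
  out <- file.path(root, "run")
  m <- run_train(list(dataset_dir = data_dir, output_dir = out,
                      method = "pix2pix", image_size = 32L,
                      base_channels = 4L, epochs = 1L, seed = 0L))
  expect_s3_class(m, "pix2pix_translator")
  expect_true(file.exists(file.path(out, "checkpoint.rds")))
  log <- utils::read.csv(file.path(out, "loss_log.csv"))
  expect_equal(nrow(log), 1)
  expect_named(log, c("epoch", "d_loss", "g_adv", "g_l1", "g_total"))

  out0 <- file.path(root, "run0")
  m0 <- run_train(list(dataset_dir = data_dir, output_dir = out0,
                       method = "unet", image_size = 32L, base_channels = 2L,
                       epochs = 0L, seed = 0L))
  expect_equal(nrow(utils::read.csv(file.path(out0, "loss_log.csv"))), 0)
  expect_true(file.exists(file.path(out0, "checkpoint.rds")))

  expect_error(run_train(list(dataset_dir = file.path(root, "nope"),
                              output_dir = out)), "dataset")
})

test_that("segment command writes one mask per image; classical methods need no checkpoint", {
  root <- withr::local_tempdir()
  data_dir <- file.path(root, "data")
  run_phantom(small_cfg(data_dir))
  masks_dir <- file.path(root, "otsu_masks")
  run_segment(list(images_dir = file.path(data_dir, "test", "images"),
                   output_dir = masks_dir, method = "otsu"))
  expect_length(list.files(masks_dir, pattern = "\\.png$"), 2)

  # reruns are bit-identical
  masks2 <- file.path(root, "otsu_masks2")
  run_segment(list(images_dir = file.path(data_dir, "test", "images"),
                   output_dir = masks2, method = "otsu"))
  f <- list.files(masks_dir, pattern = "\\.png$")[1]
  expect_identical(readBin(file.path(masks_dir, f), "raw", 1e6),
                   readBin(file.path(masks2, f), "raw", 1e6))

  expect_error(run_segment(list(images_dir = file.path(data_dir, "test", "images"),
                                output_dir = masks2, method = "pix2pix")),
               "checkpoint")
})

test_that("evaluate command matches summarize_metrics and flags orphans", {
  root <- withr::local_tempdir()
  data_dir <- file.path(root, "data")
  run_phantom(small_cfg(data_dir))
  ref_dir <- file.path(data_dir, "test", "masks")
  ev <- run_evaluate(ref_dir, ref_dir, output_dir = file.path(root, "eval"))
  expect_equal(nrow(ev$records), 2)
  expect_true(all(ev$records$f_measure == 1))
  expect_true(all(ev$summary$mean == 1))
  expect_equal(ev$summary[ev$summary$metric == "overlap", ],
               summarize_metrics(ev$records, "overlap"), ignore_attr = TRUE)
  expect_true(file.exists(file.path(root, "eval", "per_image.csv")))

  pred_dir <- file.path(root, "preds")
  dir.create(pred_dir)
  file.copy(list.files(ref_dir, full.names = TRUE)[1], pred_dir)
  expect_error(run_evaluate(pred_dir, ref_dir), "unmatched")
})

test_that("classical-only comparison runs without training", {
  res <- run_compare(list(methods = c("otsu", "canny"), n_train = 0L,
                          n_test = 3L, image_size = 32L, seed = 2L))
  expect_equal(nrow(res$table), 2)
  expect_setequal(res$table$method, c("otsu", "canny"))
  expect_equal(res$table$f_mean[res$table$method == "otsu"],
               summarize_metrics(res$records$otsu, "f_measure")$mean)
})

test_that("label-noise command with zero corruption gives coinciding summaries", {
  res <- run_label_noise(list(fraction_corrupted = 0, n_train = 2L,
                              n_test = 2L, image_size = 32L,
                              base_channels = 2L, epochs = 0L, seed = 1L))
  expect_identical(res$summary_clean, res$summary_corrupted)
  expect_equal(nrow(res$records_clean), 2)
})
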