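# Synthetic polyp generator: determinism, geometry control, dataset layout.

test_that("a sample is a deterministic function of (seed, index)", {
  p <- synthetic_params(image_size = 64L, seed = 7L)
  r1 <- generate_sample(p, 0L)
  r2 <- generate_sample(p, 0L)
  expect_identical(r1, r2)
  r3 <- generate_sample(p, 1L)
  expect_false(identical(r1$mask, r3$mask))
  p2 <- synthetic_params(image_size = 64L, seed = 8L)
  expect_false(identical(r1$image, generate_sample(p2, 0L)$image))
})

test_that("samples have sane structure: nonempty exact masks, bounded images", {
  p <- synthetic_params(image_size = 96L, seed = 3L)
  for (i in 0:4) {
    r <- generate_sample(p, i)
    expect_equal(dim(r$image), c(96L, 96L, 3L))
    expect_equal(dim(r$mask), c(96L, 96L))
    expect_true(all(r$mask %in% c(0, 1)))
    expect_gt(sum(r$mask), 0)
    expect_true(all(r$image >= 0 & r$image <= 1))
    expect_identical(r$mask, render_mask(r$meta, c(96L, 96L)))
  }
})

test_that("a fixed area fraction lands in the tolerance band around its target", {
  p <- synthetic_params(image_size = 96L, n_blobs = c(1L, 1L),
                        blob_area_fraction = c(0.01, 0.01), seed = 5L)
  fr <- vapply(0:99, function(i) mean(generate_sample(p, i)$mask), numeric(1))
  expect_true(all(fr >= 0.005 & fr <= 0.02))
})

test_that("blob count bounds the number of connected components", {
  # 4-connected flood-fill labeling, self-contained
  n_components <- function(mask) {
    H <- nrow(mask); W <- ncol(mask)
    seen <- matrix(FALSE, H, W)
    ncomp <- 0L
    for (start in which(mask == 1)) {
      if (seen[start]) next
      ncomp <- ncomp + 1L
      stack <- start
      while (length(stack)) {
        k <- stack[length(stack)]; stack <- stack[-length(stack)]
        if (seen[k]) next
        seen[k] <- TRUE
        r <- (k - 1L) %% H + 1L; c <- (k - 1L) %/% H + 1L
        for (nb in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
          if (nb[1] >= 1L && nb[1] <= H && nb[2] >= 1L && nb[2] <= W) {
            j <- nb[1] + H * (nb[2] - 1L)
            if (mask[j] == 1 && !seen[j]) stack <- c(stack, j)
          }
        }
      }
    }
    ncomp
  }
  p <- synthetic_params(image_size = 96L, n_blobs = c(2L, 2L), seed = 9L)
  for (i in 0:9) {
    r <- generate_sample(p, i)
    ncomp <- n_components(r$mask)
    expect_lte(ncomp, 2L)
    expect_gte(ncomp, 1L)
  }
})

test_that("sampled sizes cover the configured log-uniform range", {
  p <- synthetic_params(image_size = 64L, n_blobs = c(1L, 1L),
                        blob_area_fraction = c(0.002, 0.25), seed = 11L)
  target <- vapply(0:499, function(i) {
    generate_sample(p, i)$meta$blobs[[1]]$area_fraction
  }, numeric(1))
  # KS against the log-uniform law the sampler declares
  ks <- stats::ks.test(log(target), "punif", log(0.002), log(0.25))
  expect_gt(ks$p.value, 1e-3)
  # and measured mask areas track the sampled parameter
  measured <- vapply(0:49, function(i) mean(generate_sample(p, i)$mask), numeric(1))
  ratio <- measured / target[1:50]
  expect_gt(stats::median(ratio), 0.7)
  expect_lt(stats::median(ratio), 1.4)
})

test_that("dataset writing is reproducible byte for byte with a manifest", {
  p <- synthetic_params(image_size = 48L, seed = 13L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generate_dataset(p, 4L, d1)
  m2 <- generate_dataset(p, 4L, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  expect_length(list.files(file.path(d1, "images")), 4L)
  for (f in grep("png$", f1, value = TRUE)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_length(man$samples, 4L)
  expect_equal(vapply(man$samples, `[[`, character(1), "split"),
               c("train", "test", "train", "test"))
  # manifest metadata re-renders the stored mask exactly
  s1 <- man$samples[[1]]
  blobs <- lapply(s1$blobs, function(b) lapply(b, unlist))
  mk <- render_mask(list(blobs = blobs), c(48L, 48L))
  expect_identical(mk, read_mask_png(file.path(d1, "masks", s1$file)))
})

test_that("infeasible geometry fails with an informative error", {
  p <- synthetic_params(image_size = 16L, blob_area_fraction = c(0.9, 0.95),
                        seed = 1L)
  expect_error(generate_sample(p, 0L), "100 attempts")
})
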