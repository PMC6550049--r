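test_that("CSV round trips are lossless in both dialects", {
  set.seed(11)
  tpl <- make_template_form("mandible_16", seed = 5)
  ds <- simulate_group(tpl, 4, 0.05, "mutant", seed = 2)

  long <- withr::local_tempfile(fileext = ".csv")
  write_landmark_table(ds, long, "long")
  back <- read_landmark_table(long, "long")
  expect_identical(back$coords, ds$coords)
  expect_identical(back$groups, ds$groups)
  expect_identical(landmark_labels(back), landmark_labels(ds))

  wide <- withr::local_tempfile(fileext = ".csv")
  write_landmark_table(back, wide, "wide")
  back2 <- read_landmark_table(wide, "wide")
  expect_identical(back2$coords, ds$coords)

  # long -> wide -> long chain preserves coordinates
  long2 <- withr::local_tempfile(fileext = ".csv")
  write_landmark_table(back2, long2, "long")
  expect_identical(read_landmark_table(long2)$coords, ds$coords)
})

test_that("table validation names the offending specimen and landmark", {
  df <- expand.grid(landmark = c("cdl", "cds", "cor"),
                    specimen = c("S1", "S2"), stringsAsFactors = FALSE)
  df$group <- "mutant"
  set.seed(4)
  df$x <- rnorm(6); df$y <- rnorm(6); df$z <- rnorm(6)
  df <- df[c("specimen", "group", "landmark", "x", "y", "z")]

  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  ds <- read_landmark_table(f)
  expect_equal(n_specimens(ds), 2)
  expect_equal(landmark_labels(ds), c("cdl", "cds", "cor"))

  # specimen S2 lacks landmark cdl
  write.csv(df[-4, ], f, row.names = FALSE)
  expect_error(read_landmark_table(f), "S2.*cdl")

  # non-numeric coordinate
  df2 <- df; df2$y[5] <- "oops"
  write.csv(df2, f, row.names = FALSE)
  expect_error(read_landmark_table(f), "non-numeric.*S2")

  # empty coordinate
  df3 <- df; df3$z[2] <- ""
  write.csv(df3, f, row.names = FALSE)
  expect_error(read_landmark_table(f), "missing z.*S1.*cds")

  # duplicated (specimen, landmark)
  write.csv(rbind(df, df[1, ]), f, row.names = FALSE)
  expect_error(read_landmark_table(f), "duplicated")

  expect_error(read_landmark_table("no/such/file.csv"), "not found")
  expect_error(write_landmark_table(list(), f), "not a landmark_dataset")
})

test_that("trial averaging takes the per-axis mean with advisory QC flags", {
  base <- landmark_dataset(right_triangle(), "g")

  # identical trials: average is the trial itself, nothing flagged
  out <- average_digitization_trials(base, base)
  expect_identical(out$dataset$coords, base$coords)
  expect_equal(out$qc$max_displacement, 0)
  expect_equal(nrow(out$qc$flagged), 0)

  # 0.02 mm displacement on one landmark: averaged, below the 0.05 mm limit
  shifted <- base
  shifted$coords["A", "x", 1] <- 0.02
  out <- average_digitization_trials(base, shifted)
  expect_equal(out$dataset$coords["A", , 1], c(x = 0.01, y = 0, z = 0))
  expect_equal(out$qc$max_displacement, 0.02)
  expect_equal(nrow(out$qc$flagged), 0)

  # 0.06 mm displacement exceeds the 0.05 mm placement-error limit
  shifted$coords["A", "x", 1] <- 0.06
  out <- average_digitization_trials(base, shifted)
  expect_equal(out$qc$flagged$landmark, "A")
  expect_equal(out$qc$flagged$displacement, 0.06)

  # symmetric in its two arguments
  rev <- average_digitization_trials(shifted, base)
  expect_identical(rev$dataset$coords, out$dataset$coords)
  expect_identical(rev$qc$flagged, out$qc$flagged)

  other <- landmark_dataset(right_triangle() + 1, "g")
  dimnames(other$coords)[[3]] <- "zz"
  expect_error(average_digitization_trials(base, other), "specimen sets")
})

test_that("subset extraction preserves groups and matches the full form matrix", {
  tpl <- make_template_form("mandible_16", seed = 5)
  big <- rbind(tpl, sweep(tpl, 2, c(0, 10, 0), "+"))
  rownames(big) <- c(paste0("L_", rownames(tpl)), paste0("R_", rownames(tpl)))
  ds <- simulate_group(big, 3, 0.02, "mutant", seed = 9)

  hemi <- extract_subset(ds, paste0("L_", rownames(tpl)))
  expect_equal(n_landmarks(hemi), 16)
  fm <- compute_form_matrix(hemi, specimen_ids(hemi)[1])
  expect_length(fm$distances, 120)  # 16*15/2
  expect_identical(specimen_groups(hemi), specimen_groups(ds))

  # subset entries equal the corresponding entries of the full form matrix
  full <- compute_form_matrix(ds, specimen_ids(ds)[1])
  key <- paste(full$pairs$landmark_i, full$pairs$landmark_j)
  sub_key <- paste(fm$pairs$landmark_i, fm$pairs$landmark_j)
  expect_identical(fm$distances, full$distances[match(sub_key, key)])

  # full label set: unchanged up to landmark order
  same <- extract_subset(ds, rownames(big))
  expect_identical(same$coords, ds$coords)

  expect_error(extract_subset(ds, c("L_bod_01", "L_bod_02")), "fewer than 3")
  expect_error(extract_subset(ds, c("L_bod_01", "L_bod_02", "nope")), "nope")
  expect_error(subset_definition("tiny", c("a", "b")), "fewer than 3")
})

test_that("bilateral matching relabels right landmarks onto left homologs", {
  tpl <- symmetric_template()
  ds <- landmark_dataset(tpl, "wt")
  sides <- match_bilateral(ds, bilateral_pairing())

  expect_identical(landmark_labels(sides$left), landmark_labels(sides$right))
  fml <- compute_form_matrix(sides$left, specimen_ids(ds)[1])
  fmr <- compute_form_matrix(sides$right, specimen_ids(ds)[1])
  # mirror symmetry: reflection leaves all inter-landmark distances intact
  expect_equal(fml$distances, fmr$distances, tolerance = 1e-10)

  # right side scaled x1.1 about the origin: all side ratios become 1.1
  scaled <- tpl
  scaled[sprintf("R%d", 1:5), ] <- scaled[sprintf("R%d", 1:5), ] * 1.1
  sides2 <- match_bilateral(landmark_dataset(scaled, "wt"), bilateral_pairing())
  fdm <- compute_fdm(compute_form_matrix(sides2$right, specimen_ids(ds)[1]),
                     compute_form_matrix(sides2$left, specimen_ids(ds)[1]))
  expect_equal(fdm$ratios, rep(1.1, 10), tolerance = 1e-10)

  bad <- bilateral_pairing(); bad$right[2] <- "R9"
  expect_error(match_bilateral(ds, bad), "R9")
  dup <- bilateral_pairing(); dup$left[2] <- "L1"
  expect_error(match_bilateral(ds, dup), "one-to-one")
})

test_that("subset and pairing definition files parse from YAML and CSV", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("ramus: [a, b, c, d]", "body: [e, f, g]"), yml)
  subs <- read_subset_definitions(yml)
  expect_named(subs, c("ramus", "body"))
  expect_equal(subs$ramus$labels, c("a", "b", "c", "d"))

  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(name = rep("ramus", 3), label = c("a", "b", "c")),
            csv, row.names = FALSE)
  expect_equal(read_subset_definitions(csv)$ramus$labels, c("a", "b", "c"))

  pcsv <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(left = c("L1", "L2"), right = c("R1", "R2")),
            pcsv, row.names = FALSE)
  expect_equal(read_bilateral_pairing(pcsv)$right, c("R1", "R2"))

  pyml <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("L1: R1", "L2: R2"), pyml)
  expect_equal(read_bilateral_pairing(pyml),
               data.frame(left = c("L1", "L2"), right = c("R1", "R2"),
                          stringsAsFactors = FALSE))
})
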