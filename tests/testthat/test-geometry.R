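test_that("majority-vote labeling follows counts, tie rule and unknown handling", {
  # unanimous cube
  vol <- label_volume(array(7L, c(5, 5, 5)), c(`7` = "FUSIFORM"))
  expect_identical(assign_anatomical_label(c(2, 2, 2), vol), "FUSIFORM")

  # 14 voxels of code 3 vs 13 of code 5: brute-force count decides
  cube <- array(0L, c(3, 3, 3))
  cube[seq_len(14)] <- 3L
  cube[15:27] <- 5L
  vol2 <- label_volume(cube, c(`3` = "INSULA", `5` = "AMYGDALA"))
  expect_identical(assign_anatomical_label(c(1, 1, 1), vol2), "INSULA")

  # 13 vs 13 with one unknown: smallest code wins the tie
  cube3 <- array(0L, c(3, 3, 3))
  cube3[seq_len(13)] <- 3L
  cube3[14:26] <- 5L
  vol3 <- label_volume(cube3, c(`3` = "INSULA", `5` = "AMYGDALA"))
  expect_identical(assign_anatomical_label(c(1, 1, 1), vol3), "INSULA")

  # unknown never beats a named label even when it has the most voxels
  cube4 <- array(0L, c(3, 3, 3))
  cube4[1] <- 9L
  vol4 <- label_volume(cube4, c(`9` = "LINGUAL"))
  expect_identical(assign_anatomical_label(c(1, 1, 1), vol4), "LINGUAL")

  # all-unknown cube
  vol5 <- label_volume(array(0L, c(3, 3, 3)), c(`1` = "unused"))
  expect_identical(assign_anatomical_label(c(1, 1, 1), vol5), "unknown")

  # out-of-bounds center names the index
  expect_error(assign_anatomical_label(c(9, 0, 0), vol), "9")
})

test_that("labeling agrees with an exhaustive 27-voxel counting oracle", {
  oracle <- function(idx0, vol) {
    dims <- dim(vol$voxels)
    votes <- integer(0)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      p <- idx0 + c(dx, dy, dz) + 1L
      if (all(p >= 1) && all(p <= dims)) {
        votes <- c(votes, vol$voxels[p[1], p[2], p[3]])
      }
    }
    votes <- votes[votes != 0]
    if (!length(votes)) return("unknown")
    tab <- table(votes)
    best <- max(tab)
    win <- min(as.integer(names(tab)[tab == best]))
    unname(vol$code_to_name[as.character(win)])
  }
  set.seed(42)
  for (rep in 1:20) {
    vox <- array(sample(0:4, 6 * 6 * 6, replace = TRUE), c(6, 6, 6))
    vol <- label_volume(vox, setNames(paste0("S", 1:4), 1:4))
    for (i in 1:5) {
      idx <- sample(0:5, 3, replace = TRUE)
      expect_identical(assign_anatomical_label(idx, vol), oracle(idx, vol))
    }
  }
})

test_that("neighborhoods form closed per-subject balls", {
  # lone contact
  nb1 <- build_neighborhoods(contact_row(), radius_mm = 10)
  expect_identical(nb1$members[[1]], "A1")

  # adjacent contacts 3.5 mm apart are mutual members at the default radius
  two <- dplyr::bind_rows(contact_row(contact = "A1", x = 0),
                          contact_row(contact = "A2", x = 3.5))
  nb2 <- build_neighborhoods(two, radius_mm = 25)
  expect_setequal(nb2$members[[1]], c("A1", "A2"))
  expect_setequal(nb2$members[[2]], c("A1", "A2"))

  # boundary: exactly 25 mm is included (closed ball)
  far <- dplyr::bind_rows(contact_row(contact = "A1", x = 0),
                          contact_row(contact = "A2", x = 25))
  nb3 <- build_neighborhoods(far, radius_mm = 25)
  expect_setequal(nb3$members[[1]], c("A1", "A2"))

  # other subjects never join a neighborhood
  cross <- dplyr::bind_rows(contact_row(subject = "S1"),
                            contact_row(subject = "S2"))
  nb4 <- build_neighborhoods(cross, radius_mm = 100)
  expect_identical(lengths(nb4$members), c(1L, 1L))
})

test_that("neighborhood symmetry, reflexivity and radius monotonicity hold", {
  set.seed(7)
  tbl <- contact_row(contact = paste0("c", 1:30),
                     x = runif(30, -40, 0), y = runif(30, -30, 30),
                     z = runif(30, -20, 40))
  for (r in c(5, 15, 25)) {
    nb <- build_neighborhoods(tbl, r)
    for (i in seq_len(nrow(nb))) {
      expect_true(nb$contact[i] %in% nb$members[[i]])
      for (m in nb$members[[i]]) {
        j <- which(nb$contact == m)
        expect_true(nb$contact[i] %in% nb$members[[j]])
      }
    }
  }
  nb_small <- build_neighborhoods(tbl, 10)
  nb_big <- build_neighborhoods(tbl, 20)
  for (i in seq_len(nrow(nb_small))) {
    expect_true(all(nb_small$members[[i]] %in% nb_big$members[[i]]))
  }
})

test_that("coverage summary counts partition the cohort and match the reference table", {
  ref <- structure_counts_reference()
  # rebuild a contact table with one row per implanted contact
  rows <- ref[rep(seq_len(nrow(ref)), ref$implanted), ]
  contacts <- tibble::tibble(
    subject = "GROUP", contact = paste0("c", seq_len(nrow(rows))),
    x = ifelse(rows$hemisphere == "LH", -10, 10), y = 0, z = 0,
    label = rows$structure, hemisphere = rows$hemisphere
  )
  cov <- coverage_summary(contacts)
  totals <- attr(cov, "totals")
  expect_equal(totals$n_contacts[totals$hemisphere == "LH"], 531)
  expect_equal(totals$n_contacts[totals$hemisphere == "RH"], 473)
  expect_equal(sum(cov$n_contacts), 1004)

  # permutation of rows does not change the summary
  cov2 <- coverage_summary(contacts[sample(nrow(contacts)), ])
  expect_equal(as.data.frame(cov2), as.data.frame(cov))

  # empty table and one-contact-per-structure edge cases
  empty <- contacts[0, ]
  expect_equal(nrow(coverage_summary(empty)), 0)
  singles <- dplyr::distinct(contacts, label, hemisphere, .keep_all = TRUE)
  cov3 <- coverage_summary(singles)
  expect_true(all(cov3$n_contacts == 1))
})
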