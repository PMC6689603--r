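test_that("NEXUS matrices read with missing, gap and polymorphic cells", {
  path <- write_tmp_nexus(list(A = "01", B = "0?", C = "10"))
  m <- read_character_matrix(path)
  expect_equal(length(m$taxa), 3L)
  expect_equal(m$nchar, 2L)
  expect_equal(m$cells[[1]][[1]], 0L)          # A char 1
  expect_equal(m$cells[[2]][[2]], c(0L, 1L))   # B char 2 missing -> full set
  expect_equal(m$cells[[1]][[3]], 1L)

  path2 <- write_tmp_nexus(list(A = "(01)0", B = "00", C = "-1"))
  m2 <- read_character_matrix(path2)
  expect_equal(m2$cells[[1]][[1]], c(0L, 1L))  # polymorphic
  expect_equal(m2$cells[[1]][[3]], c(0L, 1L))  # gap = full ambiguity
})

test_that("matrix round-trips through NEXUS", {
  set.seed(5)
  cells <- lapply(1:6, function(j) {
    k <- sample(2:4, 1)
    lapply(1:5, function(i) {
      r <- runif(1)
      if (r < 0.15) 0:(k - 1L)
      else if (r < 0.3) sort(sample(0:(k - 1L), 2L))
      else sample(0:(k - 1L), 1L)
    })
  })
  m <- character_matrix(cells, paste0("t", 1:5),
                        ordered = c(TRUE, rep(FALSE, 5)))
  path <- tempfile(fileext = ".nex")
  write_character_matrix(m, path)
  m2 <- read_character_matrix(path, ordered = which(m$ordered))
  # state sets must survive (state counts can only be inferred from
  # observations, so compare cells under the original k)
  for (j in seq_len(m$nchar)) {
    for (i in seq_along(m$taxa)) {
      s1 <- m$cells[[j]][[i]]
      s2 <- m2$cells[[j]][[i]]
      if (length(s1) == m$state_count[j]) {
        expect_gte(length(s2), m2$state_count[j])
      } else {
        expect_equal(s2, s1)
      }
    }
  }
  expect_equal(m2$ordered, m$ordered)
})

test_that("duplicate taxa and out-of-range symbols are rejected", {
  expect_error(character_matrix(list(list(0L, 0L)), c("a", "a")),
               "duplicate")
  expect_error(character_matrix(list(list(0L, 5L)), c("a", "b"),
                                state_count = 2L), "outside")
  path <- write_tmp_nexus(list(A = "02", B = "00"), symbols = "01")
  expect_error(read_character_matrix(path), "SYMBOLS")
})

test_that("classify_characters counts binary/multistate/ordered and is
           invariant to taxon order", {
  cells <- list(
    lapply(c(0L, 1L, 0L), identity),            # binary
    lapply(c(0L, 1L, 2L), identity),            # multistate
    lapply(c(0L, 2L, 0L), identity),            # two observed states
    lapply(c(1L, 0L, 1L), identity))
  m <- character_matrix(cells, c("a", "b", "c"),
                        ordered = c(FALSE, TRUE, FALSE, FALSE))
  cl <- classify_characters(m)
  expect_equal(cl$n_binary, 3L)
  expect_equal(cl$n_multistate, 1L)
  expect_equal(cl$n_ordered, 1L)

  perm <- c(3L, 1L, 2L)
  m2 <- character_matrix(lapply(cells, function(col) col[perm]),
                         c("c", "a", "b"),
                         ordered = m$ordered)
  expect_equal(classify_characters(m2)[c("n_binary", "n_multistate")],
               cl[c("n_binary", "n_multistate")])
})

test_that("partition assignment covers characters exactly once", {
  cells <- lapply(1:4, function(j) lapply(c(0L, 1L), identity))
  m <- character_matrix(cells, c("a", "b"))
  m2 <- assign_partitions(m, list(head = "1-2", tail = c(3, 4)))
  expect_equal(unname(classify_characters(m2)$partition_sizes), c(2L, 2L))
  expect_equal(sum(classify_characters(m2)$partition_sizes), m$nchar)
  expect_error(assign_partitions(m, list(head = "1-2", tail = 3)),
               "cover")
  expect_error(assign_partitions(m, list(head = "1-3", tail = "3-4")),
               "more than one")
})

test_that("tip calibrations validate ranges and extant flags", {
  tc <- tip_calibrations(c("x", "y", "z"), c(0, 66, 10), c(0, 167.7, 20))
  expect_true(tc$is_extant[1])
  expect_false(tc$is_extant[2])
  expect_error(tip_calibrations("x", 100, 90), "age_min")
  expect_error(tip_calibrations("x", -5, 10), "negative")
  path <- tempfile(fileext = ".tsv")
  writeLines(c("taxon\tage_min\tage_max", "a\t0\t0", "b\t66\t167.7"), path)
  tab <- read_tip_calibrations(path, taxa = c("a", "b"))
  expect_equal(tab$age_max[2], 167.7)
  expect_error(read_tip_calibrations(path, taxa = c("a", "b", "c")),
               "without calibration")
})

test_that("constraint sets must nest or be disjoint", {
  taxa <- letters[1:6]
  expect_silent(constraint_set(list(A = c("a", "b", "c"), B = c("a", "b"),
                                    C = c("d", "e")), taxa))
  expect_error(constraint_set(list(A = c("a", "b", "c"),
                                   B = c("c", "d")), taxa),
               "overlap")
  expect_error(constraint_set(list(A = taxa), taxa), "proper subset")
})

test_that("analysis config files parse partitions, ordering, constraints", {
  path <- tempfile(fileext = ".yml")
  writeLines(c("partitions:", "  skull: 1-3", "  rest: 4-6",
               "ordered: 2 5-6",
               "constraints:", "  CladeA: [t1, t2]"), path)
  cfg <- read_analysis_config(path)
  expect_equal(cfg$partitions$skull, "1-3")
  expect_equal(cfg$ordered, c(2L, 5L, 6L))
  expect_equal(cfg$constraints$CladeA, c("t1", "t2"))
})
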