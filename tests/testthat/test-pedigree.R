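test_that("pedigree construction validates, orders, and inserts founders", {
  # minimal pedigree, input out of order: topological order restored
  p <- pedigree(c("C", "A", "B"), c("A", NA, NA), c("B", NA, NA))
  expect_s3_class(p, "pedigree")
  expect_equal(nrow(p), 3L)
  expect_lt(match("A", p$id), match("C", p$id))
  expect_lt(match("B", p$id), match("C", p$id))

  # referenced-but-absent parents materialize as founders
  expect_message(p2 <- pedigree("C", "A", "B"), "inserted as founders")
  expect_setequal(p2$id, c("A", "B", "C"))
  expect_true(all(is.na(p2[p2$id == "A", c("parent1", "parent2")])))

  # unknown tokens normalize
  p3 <- pedigree(c("A", "B"), c("0", "NA"), c("", "unknown"))
  expect_true(all(is.na(p3$parent1)) && all(is.na(p3$parent2)))

  # errors: duplicates, self-parent, cycles
  expect_error(pedigree(c("A", "A"), c(NA, NA), c(NA, NA)), "duplicate")
  expect_error(pedigree("A", "A", NA), "own parent")
  expect_error(suppressMessages(
    pedigree(c("C", "A"), c("A", "C"), c("B", NA))), "cycle")
})

test_that("pedigree CSV round trip preserves records", {
  p <- toy_ped()
  f <- tempfile(fileext = ".csv")
  write_pedigree(p, f)
  p2 <- read_pedigree(f)
  expect_equal(as.data.frame(p2), as.data.frame(p))
  expect_error(read_pedigree(tempfile()), "no such file")
})

test_that("trace returns the ancestor closure, idempotently", {
  p <- suppressMessages(
    pedigree(c("A", "B", "C", "D"), c(NA, NA, "A", "A"),
             c(NA, NA, "B", NA)))
  tr <- trace_pedigree(p, "C")
  expect_setequal(tr$id, c("A", "B", "C"))
  # identity when all ids are focal
  expect_equal(as.data.frame(trace_pedigree(p, p$id)), as.data.frame(p))
  # idempotence
  expect_equal(as.data.frame(trace_pedigree(tr, "C")),
               as.data.frame(tr))
  expect_error(trace_pedigree(p, "nope"), "not in pedigree")

  # 4-generation chain: tracing the terminal id keeps every ancestor,
  # cross-checked against brute-force ancestor enumeration
  ch <- chain_ped(4)
  anc <- function(ped, id) {
    out <- id
    repeat {
      par <- unique(stats::na.omit(c(
        ped$parent1[ped$id %in% out], ped$parent2[ped$id %in% out])))
      new <- setdiff(par, out)
      if (!length(new)) return(out)
      out <- c(out, new)
    }
  }
  expect_setequal(trace_pedigree(ch, "G4")$id, anc(ch, "G4"))
})

test_that("completeness reproduces the anchor cases and the recursion", {
  # both parents known founders -> 1
  p1 <- pedigree(c("A", "B", "X"), c(NA, NA, "A"), c(NA, NA, "B"))
  expect_equal(unname(completeness(p1)$per_id["X"]), 1)
  # all four grandparents known founders -> 2
  p2 <- pedigree(c("A", "B", "C", "D", "S", "Dm", "X"),
                 c(NA, NA, NA, NA, "A", "C", "S"),
                 c(NA, NA, NA, NA, "B", "D", "Dm"))
  expect_equal(unname(completeness(p2)$per_id["X"]), 2)
  # one parent known founder, other unknown -> 0.5
  p3 <- pedigree(c("A", "X"), c(NA, "A"), c(NA, NA))
  expect_equal(unname(completeness(p3)$per_id["X"]), 0.5)
  # founders score 0; perfect g-generation chains with unknown-parent
  # gaps handled by the fractional recursion
  cs <- completeness(p1)
  expect_equal(unname(cs$per_id[c("A", "B")]), c(0, 0))
  expect_true(cs$mean <= cs$max)
  expect_equal(cs$frac_unknown_parents, 2 / 3)

  # upgrading an UNKNOWN parent to a known founder strictly increases
  # the focal line's completeness
  p4 <- suppressMessages(pedigree(c("X", "F1"), c("F1", NA), c(NA, NA)))
  p5 <- suppressMessages(
    pedigree(c("X", "F1", "F2"), c("F1", NA, NA), c("F2", NA, NA)))
  expect_gt(completeness(p5)$per_id["X"], completeness(p4)$per_id["X"])
})

test_that("completeness matches independent recursion on a random pedigree", {
  p <- rand_ped(50, 12, seed = 42)
  # memoised reference recursion written independently of the package
  ref <- local({
    memo <- new.env()
    p1 <- stats::setNames(p$parent1, p$id)
    p2 <- stats::setNames(p$parent2, p$id)
    comp <- function(id) {
      if (!is.null(memo[[id]])) return(memo[[id]])
      v <- 0
      for (par in c(p1[[id]], p2[[id]]))
        if (!is.na(par)) v <- v + (1 + comp(par)) / 2
      memo[[id]] <- v
      v
    }
    vapply(p$id, comp, 0)
  })
  cs <- completeness(p)
  expect_equal(cs$per_id[names(ref)], ref, tolerance = 1e-12)
  expect_equal(cs$mean, mean(ref))
  expect_equal(cs$max, max(ref))
})

test_that("a perfect g-generation pedigree has terminal completeness g", {
  # full binary ancestry of depth g, all founders known
  for (g in 1:5) {
    ids <- "T"; p1 <- NA_character_; p2 <- NA_character_
    level <- "T"
    for (d in seq_len(g)) {
      newlev <- character(0)
      for (x in level) {
        a <- paste0(x, "s"); b <- paste0(x, "d")
        p1[match(x, ids)] <- a; p2[match(x, ids)] <- b
        ids <- c(ids, a, b); p1 <- c(p1, NA, NA); p2 <- c(p2, NA, NA)
        newlev <- c(newlev, a, b)
      }
      level <- newlev
    }
    ped <- pedigree(ids, p1, p2)
    expect_equal(unname(completeness(ped)$per_id["T"]), g)
  }
})

test_that("breeding cycles partition lines by crossing year", {
  p <- pedigree(c("A", "B", "C"), c(NA, NA, NA), c(NA, NA, NA),
                crossing_year = c(2003, 2003, 2004))
  cyc <- breeding_cycles(p)
  expect_length(cyc, 2L)
  expect_setequal(cyc[["2003"]], c("A", "B"))
  # single year -> one cycle
  p1 <- pedigree("A", NA, NA, 2000)
  expect_length(breeding_cycles(p1), 1L)
  # missing years excluded with warning; all missing errors
  p2 <- pedigree(c("A", "B"), c(NA, NA), c(NA, NA), c(2000, NA))
  expect_warning(cy <- breeding_cycles(p2), "excluded")
  expect_length(cy, 1L)
  p3 <- pedigree("A", NA, NA)
  expect_error(breeding_cycles(p3), "no crossing years")
})

test_that("a simulated multi-cycle program yields one cycle per year", {
  cfg <- sim_config(n_founders = 8, n_cycles = 28, crosses_per_cycle = 2,
                    progeny_per_cross = 2, selection_fraction = 0.5)
  ped <- simulate_pedigree(cfg, seed = 1)
  # founders carry no crossing year and are excluded from the cycles
  expect_warning(cyc <- breeding_cycles(ped), "excluded")
  expect_length(cyc, 28L)
  # every non-founder has both parents known
  nf <- !(is.na(ped$parent1) & is.na(ped$parent2))
  expect_true(all(!is.na(ped$parent1[nf]) & !is.na(ped$parent2[nf])))
  expect_true(all(completeness(ped)$per_id[nf] >= 1))
})
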