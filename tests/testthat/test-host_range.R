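mk_eop <- function(values, iso, ...) {
  eop_matrix(values, iso, ...)
}

test_that("EOP normalization: isolation host to 1, substitute titer, errors", {
  v <- matrix(c(2e8, 2e6, 0,
                1e7, 1e7, 1e7), 2, 3, byrow = TRUE,
              dimnames = list(c("v1", "v2"), c("h1", "h2", "h3")))
  m <- mk_eop(v, c(v1 = "h1", v2 = "h2"))
  nm <- normalize_eop(m)
  expect_equal(nm$values["v1", "h1"], 1)
  expect_equal(nm$values["v1", "h2"], 1e-2)
  expect_equal(unname(nm$values["v2", ]), c(1, 1, 1))
  # idempotent
  expect_equal(normalize_eop(nm)$values, nm$values)
  # scale invariance of a row
  v2 <- v
  v2["v1", ] <- v2["v1", ] * 10
  nm2 <- normalize_eop(mk_eop(v2, c(v1 = "h1", v2 = "h2")))
  expect_equal(nm2$values["v1", ], nm$values["v1", ])
  # substitute titer for a virus whose reference host is off-panel
  # (externally measured 2e8 pfu/mL treated as EOP 1)
  v3 <- matrix(c(2e8, 2e6), 1, 2,
               dimnames = list("v3", c("h1", "h2")))
  m3 <- mk_eop(v3, c(v3 = "offpanel"), substitute_titer = c(v3 = 2e8))
  n3 <- normalize_eop(m3)
  expect_equal(unname(n3$values["v3", ]), c(1, 1e-2))
  # zero isolation titer without substitute -> error
  v4 <- matrix(c(0, 5e6), 1, 2, dimnames = list("v4", c("h1", "h2")))
  expect_error(normalize_eop(mk_eop(v4, c(v4 = "h1"))), "zero or missing")
})

test_that("detection floor zeroes sub-detectable raw titers", {
  v <- matrix(c(2e8, 500, 1e3), 1, 3,
              dimnames = list("v1", c("h1", "h2", "h3")))
  m <- mk_eop(v, c(v1 = "h1"))
  expect_equal(unname(m$values["v1", ]), c(2e8, 0, 1e3))
})

test_that("log10 binning follows the printed category convention", {
  expect_equal(bin_log10(1), 0L)           # displayed "1"
  expect_equal(bin_log10(10), 1L)          # displayed "+1"
  expect_equal(bin_log10(3.2e-3), -2L)
  expect_equal(bin_log10(3.2e-4), -3L)
  expect_true(is.na(bin_log10(0)))
  expect_error(bin_log10(-1), "negative")
  lab <- format_eop_category(c(0L, 1L, -2L, NA))
  expect_identical(lab, c("1", "+1", "-2", "ni"))
})

test_that("hs statistic: hand cases, symmetry, boundary", {
  expect_equal(hs(c("a", "b"), c("a", "b")), 1)
  expect_equal(hs(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(hs(c("a"), c("b")), 0)
  expect_warning(z <- hs(character(0), character(0)), "empty")
  expect_equal(z, 0)
  # symmetric, and 1 iff identical as sets
  expect_equal(hs(c("a", "b"), c("b", "a", "a")), 1)
  profiles <- list(x = c("a", "b"), y = c("b", "c"), z = c("a", "b"))
  m <- hs_matrix(profiles)
  expect_equal(m, t(m))
  expect_equal(m["x", "z"], 1)
})

test_that("host clustering groups identical columns and ignores row order", {
  cats <- matrix(c(0L, 0L, -5L,
                   -1L, -1L, NA,
                   -2L, -2L, 0L), 3, 3, byrow = TRUE,
                 dimnames = list(c("v1", "v2", "v3"), c("h1", "h2", "h3")))
  tr <- cluster_hosts(cats)
  expect_true(ape::is.monophyletic(tr, c("h1", "h2")))
  tr2 <- cluster_hosts(cats[c(3, 1, 2), ])
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)), 0,
               ignore_attr = TRUE)
})

test_that("adhesin association: perfect monotone case and invariances", {
  set.seed(701)
  ids <- sprintf("v%02d", 1:8)
  idm <- matrix(runif(64, 20, 100), 8, 8, dimnames = list(ids, ids))
  idm <- (idm + t(idm)) / 2
  diag(idm) <- 100
  hsm <- idm / 100 # hs an exact monotone function of identity
  r <- associate_adhesin(hsm, idm, n_perm = 99, seed = 5)
  expect_equal(r$overall$rho, 1)
  expect_lte(r$overall$p_value, 1 / 100)
  # duplicated virus rows leave the perfect correlation unchanged
  ids2 <- c(ids, "v01dup")
  idm2 <- rbind(cbind(idm, idm[, "v01"]), c(idm["v01", ], 100))
  dimnames(idm2) <- list(ids2, ids2)
  hsm2 <- idm2 / 100
  r2 <- associate_adhesin(hsm2, idm2, n_perm = 99, seed = 5)
  expect_equal(r2$overall$rho, 1)
  expect_error(associate_adhesin(hsm[1:3, 1:3], idm[1:3, 1:3]), "at least 4")
  expect_error(associate_adhesin(hsm, idm, n_perm = 10), ">= 99")
})

test_that("synthetic EOP: noise-free block limit and group separation", {
  noisefree <- gen_eop_matrix(leak = 0, lognormal_sigma = 0, seed = 3)
  nm <- normalize_eop(noisefree$eop)
  expect_true(all(nm$values %in% c(0, 1)))
  prof <- sensitive_hosts(nm)
  hsm <- hs_matrix(prof)
  grp <- noisefree$truth$groups[rownames(hsm)]
  same <- outer(grp, grp, "==")
  ut <- upper.tri(hsm)
  expect_true(all(hsm[ut & same] == 1))
  expect_true(all(hsm[ut & !same] == 0))
  # defaults (seed 7): within-group mean hs above across-group mean hs
  sim <- gen_eop_matrix(seed = 7)
  hsm2 <- hs_matrix(sensitive_hosts(normalize_eop(sim$eop)))
  grp2 <- sim$truth$groups[rownames(hsm2)]
  same2 <- outer(grp2, grp2, "==")
  expect_gt(mean(hsm2[ut & same2]), mean(hsm2[ut & !same2]))
  # null construction: all groups share one susceptibility map
  allsame <- setNames(rep(list(sprintf("host%02d", 1:12)), 4),
                      sprintf("G%d", 1:4))
  null <- gen_eop_matrix(group_host_susceptibility = allsame, seed = 9)
  hsm3 <- hs_matrix(sensitive_hosts(normalize_eop(null$eop)))
  grp3 <- null$truth$groups[rownames(hsm3)]
  same3 <- outer(grp3, grp3, "==")
  expect_lt(abs(mean(hsm3[ut & same3]) - mean(hsm3[ut & !same3])), 0.05)
})

test_that("EOP table I/O round-trips", {
  sim <- gen_eop_matrix(seed = 11)
  ep <- withr::local_tempfile(fileext = ".tsv")
  ip <- withr::local_tempfile(fileext = ".tsv")
  write_eop_table(sim$eop, ep)
  write.table(data.frame(sim$truth$viruses$virus,
                         sim$truth$viruses$isolation_host),
              ip, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  m <- read_eop_table(ep, ip)
  expect_equal(m$values, sim$eop$values)
  expect_equal(m$isolation_host, sim$eop$isolation_host)
})
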