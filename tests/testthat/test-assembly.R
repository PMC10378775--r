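test_that("variant subunits expose the published interface sites", {
  expect_length(make_subunit("D7H")$sites, 3L)
  expect_length(make_subunit("WT")$sites, 2L)
  expect_setequal(make_subunit("isoD7")$sites, c("E11/H14", "H6/H13"))
  expect_setequal(make_subunit("D7H")$sites, c("E11/H14", "E3/H6", "H7/H13"))
  expect_error(make_subunit("D7Q"), "unknown variant")
})

test_that("bridge validation enforces valence, compatibility and recruitment", {
  a <- new_assembly(c("D7H", "D7H", "D7H"))
  a <- add_bridge(a, c(1, "E11/H14"), c(2, "E11/H14"))
  expect_equal(zinc_count(a), 1L)
  ## occupied site
  expect_error(add_bridge(a, c(1, "E11/H14"), c(3, "E11/H14")), "occupied")
  ## self bridge
  expect_error(add_bridge(a, c(3, "E3/H6"), c(3, "H7/H13")), "itself")
  ## incompatible heterotypic pairing
  expect_error(add_bridge(a, c(1, "E3/H6"), c(2, "H7/H13")), "incompatible")
  ## unknown site for the variant
  expect_error(add_bridge(a, c(1, "H6/H13"), c(2, "H6/H13")), "has no site")
  ## WT-WT dimers are forbidden under the recruitment rule ...
  w <- new_assembly(c("WT", "WT"))
  expect_error(add_bridge(w, c(1, "E11/H14"), c(2, "E11/H14")), "recruitment")
  ## ... and WT lateral sites are inert
  wx <- new_assembly(c("WT", "D7H"))
  expect_error(add_bridge(wx, c(1, "E3/H6"), c(2, "E3/H6")), "inert")
  ## both are allowed when the rule is disabled
  w2 <- new_assembly(c("WT", "WT"), recruitment_rule = FALSE)
  expect_silent(w2 <- add_bridge(w2, c(1, "E11/H14"), c(2, "E11/H14")))
  ## strict homotypic mode blocks the heterotrimer edge
  s <- new_assembly(c("D7H", "WT"), strict_homotypic = TRUE)
  expect_error(add_bridge(s, c(1, "H7/H13"), c(2, "E11/H14")), "incompatible")
})

test_that("named topologies match the published constructions", {
  d <- build_named_assembly("dimer_EVHH")
  expect_equal(nrow(assembly_subunits(d)), 2L)
  expect_equal(zinc_count(d), 1L)

  t1 <- build_named_assembly("tetramer_E3H6")
  expect_equal(nrow(assembly_subunits(t1)), 4L)
  expect_equal(zinc_count(t1), 4L)  # two EVHH bridges + two E3/H6 bridges
  expect_equal(sum(assembly_bridges(t1)$site_a == "E3/H6"), 2L)

  t2 <- build_named_assembly("tetramer_H7H13")
  expect_equal(sum(assembly_bridges(t2)$site_a == "H7/H13"), 2L)

  oc <- build_named_assembly("octamer")
  expect_equal(nrow(assembly_subunits(oc)), 8L)

  dd <- build_named_assembly("dodecamer")
  expect_equal(nrow(assembly_subunits(dd)), 12L)
  expect_true(znoligomer:::is_connected_assembly(dd))
  ## all three interface types appear in the lattice
  sites <- unique(c(assembly_bridges(dd)$site_a, assembly_bridges(dd)$site_b))
  expect_setequal(sites, c("E11/H14", "E3/H6", "H7/H13"))

  ## heterotrimers: central modified subunit engaged through both non-E3 sites
  for (nm in c("heterotrimer_D7H", "heterotrimer_isoD7")) {
    ht <- build_named_assembly(nm)
    expect_equal(nrow(assembly_subunits(ht)), 3L)
    expect_equal(zinc_count(ht), 2L)
    br <- assembly_bridges(ht)
    central_sites <- c(br$site_a[br$sub_a == 1], br$site_b[br$sub_b == 1])
    want <- if (nm == "heterotrimer_D7H") c("E11/H14", "H7/H13")
            else c("E11/H14", "H6/H13")
    expect_setequal(central_sites, want)
    ## flanking subunits attach through E11/H14
    flank_sites <- c(br$site_a[br$sub_a != 1], br$site_b[br$sub_b != 1])
    expect_true(all(flank_sites == "E11/H14"))
  }
  expect_error(build_named_assembly("pentamer"), "arg")
})

test_that("seed counting matches the enumeration oracle on every topology", {
  for (nm in c("dimer_EVHH", "tetramer_E3H6", "tetramer_H7H13", "octamer",
               "dodecamer", "heterotrimer_D7H", "heterotrimer_isoD7")) {
    a <- build_named_assembly(nm)
    expect_equal(free_seed_count(a, "D7H"), oracle_seed_count(a, "D7H"),
                 label = nm)
  }
  ## the dodecamer exposes exactly three polymerization seeds
  expect_equal(free_seed_count(build_named_assembly("dodecamer")), 3L)
  ## a lone unmodified monomer has none
  expect_equal(free_seed_count(new_assembly("WT")), 0L)
  ## extension queries
  expect_true(can_extend(build_named_assembly("dodecamer"), "D7H"))
  expect_false(can_extend(build_named_assembly("heterotrimer_D7H"), "WT"))
  expect_false(can_extend(new_assembly(), "D7H"))
})

test_that("zinc accounting and valence survive randomized operations", {
  set.seed(99)
  for (rep in 1:10) {
    a <- new_assembly(sample(c("D7H", "WT", "isoD7"), 6, replace = TRUE,
                             prob = c(.6, .2, .2)))
    n_ok <- 0
    for (step in 1:20) {
      s1 <- sample(6, 1); s2 <- sample(6, 1)
      v1 <- znoligomer:::subunit_variant(a, s1)
      v2 <- znoligomer:::subunit_variant(a, s2)
      site1 <- sample(interface_sites(v1), 1)
      site2 <- sample(interface_sites(v2), 1)
      legal <- is.null(znoligomer:::bridge_illegality(a, s1, site1, s2, site2))
      if (legal) {
        a <- add_bridge(a, c(s1, site1), c(s2, site2))
        n_ok <- n_ok + 1
      } else {
        expect_error(add_bridge(a, c(s1, site1), c(s2, site2)))
      }
      ## invariants after every operation
      br <- assembly_bridges(a)
      expect_equal(zinc_count(a), nrow(br))
      ends <- rbind(data.frame(id = br$sub_a, site = br$site_a),
                    data.frame(id = br$sub_b, site = br$site_b))
      expect_false(any(duplicated(ends)))            # valence: one per site
      per_sub <- table(factor(ends$id, levels = 1:6))
      caps <- vapply(1:6, function(i)
        length(interface_sites(znoligomer:::subunit_variant(a, i))),
        integer(1))
      expect_true(all(as.integer(per_sub) <= caps))  # variant capacity
    }
    expect_equal(zinc_count(a), n_ok)
  }
})

test_that("upgrading WT subunits never decreases the seed count", {
  set.seed(7)
  for (rep in 1:15) {
    ## random legal growth from a modified dimer with WT recruits
    a <- build_named_assembly(sample(c("dimer_EVHH", "tetramer_E3H6",
                                       "heterotrimer_D7H"), 1))
    for (extra in 1:3) {
      a <- add_subunit(a, sample(c("WT", "D7H"), 1))
      ids <- assembly_subunits(a)$id
      new_id <- max(ids)
      ## try to attach the newcomer anywhere legal
      done <- FALSE
      for (host in sample(setdiff(ids, new_id))) {
        for (hs in interface_sites(znoligomer:::subunit_variant(a, host))) {
          for (ns in interface_sites(znoligomer:::subunit_variant(a, new_id))) {
            if (is.null(znoligomer:::bridge_illegality(a, host, hs, new_id, ns))) {
              a <- add_bridge(a, c(host, hs), c(new_id, ns)); done <- TRUE
            }
            if (done) break
          }
          if (done) break
        }
        if (done) break
      }
    }
    before <- free_seed_count(a, c("WT", "D7H"))
    b <- a
    wt_ids <- assembly_subunits(b)$id[assembly_subunits(b)$variant == "WT"]
    for (id in wt_ids) b <- set_subunit_variant(b, id, "D7H")
    after <- free_seed_count(b, c("WT", "D7H"))
    expect_gte(after, before)
  }
})

test_that("assemblies serialize to graph text and igraph", {
  a <- build_named_assembly("heterotrimer_isoD7")
  f <- tempfile(fileext = ".txt")
  write_assembly(a, f)
  txt <- readLines(f)
  expect_true(any(grepl("isoD7", txt)))
  expect_true(any(grepl("H6/H13", txt)))
  skip_if_not_installed("igraph")
  g <- assembly_to_igraph(a)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
})
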