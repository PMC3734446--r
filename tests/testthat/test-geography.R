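test_that("queen contiguity on a lattice matches brute-force enumeration", {
  l <- make_lattice(3, 3)
  un <- l$geo$units
  center <- un$id[un$row == 2 & un$col == 2]
  corner <- un$id[un$row == 1 & un$col == 1]
  expect_length(l$adj$nbr[[center]], 8)
  expect_length(l$adj$nbr[[corner]], 3)

  # independent oracle: enumerate all queen pairs directly
  pairs <- 0
  for (i in seq_len(9)) for (j in seq_len(9)) {
    if (i < j && abs(un$row[i] - un$row[j]) <= 1 && abs(un$col[i] - un$col[j]) <= 1) {
      pairs <- pairs + 1
      expect_true(un$id[j] %in% l$adj$nbr[[un$id[i]]])
    }
  }
  expect_identical(pairs, 20)
  expect_identical(n_edges(l$adj), 20)
})

test_that("adjacency constructors yield symmetric irreflexive structures", {
  for (dims in list(c(1, 1), c(2, 5), c(4, 4))) {
    adj <- make_lattice(dims[1], dims[2])$adj
    expect_silent(validate_adjacency(adj))
    expect_false(any(vapply(adj$ids, function(i) i %in% adj$nbr[[i]], logical(1))))
  }
  expect_length(make_lattice(1, 1)$adj$nbr[[1]], 0)
  expect_error(new_adjacency(c("a", "b"), list(a = "b", b = character(0))),
               "asymmetric")
})

test_that("a river severs contiguity and supplementary edges restore it", {
  geo <- generate_geography(4, 4, river = TRUE)   # river after row 2
  adj <- contiguity_adjacency(geo)
  un <- geo$units
  north <- un$id[un$row <= 2]; south <- un$id[un$row > 2]
  for (i in north) expect_length(intersect(adj$nbr[[i]], south), 0)

  expect_identical(add_supplementary_edges(adj, geo, 0), adj)
  expect_error(add_supplementary_edges(adj, geo, -1), "non-negative")

  adj2 <- add_supplementary_edges(adj, geo, 0.5)  # river width 0.3 < 0.5
  facing <- un$id[un$row == 3 & un$col == 2]
  across <- un$id[un$row == 2 & un$col == 2]
  expect_true(across %in% adj2$nbr[[facing]])
  k <- match(across, adj2$nbr[[facing]])
  expect_identical(adj2$flag[[facing]][k], "supplementary")
  expect_silent(validate_adjacency(adj2))
  expect_length(connected_components(adj2) |> unique(), 1L)
  expect_length(unique(connected_components(adj)), 2L)
})

test_that("study-area filters reproduce the three-rule accounting", {
  ids <- sprintf("U%03d", 1:297)
  flags <- data.frame(suburb_id = ids,
                      outside_area = ids %in% ids[1:7],
                      ses_available = !ids %in% ids[28:30])
  set.seed(1)
  births1 <- rpois(297, 150) + 1L
  births2 <- rpois(297, 150) + 1L
  births1[8:20] <- 0L            # zero in period 1
  births2[21:27] <- 0L           # zero in period 2
  per <- list(p1 = data.frame(suburb_id = ids, births = births1),
              p2 = data.frame(suburb_id = ids, births = births2))
  res <- apply_study_area_filters(per, flags)
  expect_identical(unname(res$counts),
                   c(7L, 20L, 3L, 267L))
  expect_identical(sum(res$counts[1:3]) + res$counts[["retained"]], 297L)
  expect_identical(nrow(res$tables$p1), 267L)

  # idempotent
  flags2 <- flags[flags$suburb_id %in% res$retained_ids, ]
  res2 <- apply_study_area_filters(res$tables, flags2)
  expect_identical(res2$counts[["retained"]], 267L)
  expect_identical(sum(res2$counts[1:3]), 0L)

  # precedence: a unit failing outside-area AND zero-births counts once, first rule
  flags$outside_area[10] <- TRUE
  res3 <- apply_study_area_filters(per, flags)
  expect_identical(res3$counts[["outside_area"]], 8L)
  expect_identical(res3$counts[["zero_births"]], 19L)
  expect_identical(sum(res3$counts), 297L)
})

test_that("restricting an adjacency never creates edges", {
  adj <- make_lattice(5, 5)$adj
  keep <- sample(adj$ids, 12)
  sub <- restrict_adjacency(adj, keep)
  for (i in sub$ids) {
    expect_true(all(sub$nbr[[i]] %in% adj$nbr[[i]]))
  }
  expect_silent(validate_adjacency(sub))
})

test_that("GAL files round-trip, including empty-neighbour units", {
  adj <- new_adjacency(c("a", "b", "c"),
                       list(a = "b", b = "a", c = character(0)))
  path <- withr::local_tempfile(fileext = ".gal")
  write_gal(adj, path)
  back <- read_gal(path)
  expect_identical(back$ids, adj$ids)
  expect_identical(back$nbr, adj$nbr)

  lat <- make_lattice(4, 3)$adj
  write_gal(lat, path)
  expect_identical(read_gal(path)$nbr, lat$nbr)

  # asymmetric file rejected with the offending pair named
  writeLines(c("2", "a 1", "b", "b 0", ""), path)
  expect_error(read_gal(path), "a->b")
})

test_that("GeoJSON geography round-trips footprints and river metadata", {
  geo <- generate_geography(3, 4, river = TRUE)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_geography_geojson(geo, path)
  back <- read_geography_geojson(path)
  expect_identical(back$units$id, geo$units$id)
  expect_equal(back$units[c("xmin", "xmax", "ymin", "ymax")],
               geo$units[c("xmin", "xmax", "ymin", "ymax")])
  expect_identical(back$river$after_row, geo$river$after_row)
  expect_identical(contiguity_adjacency(back)$nbr, contiguity_adjacency(geo)$nbr)
})
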