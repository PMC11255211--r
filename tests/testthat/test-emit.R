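# a small processed chain shared by the emission tests
emit_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    fx <- make_structure(fixture_spec(
      8, altloc_segments = data.frame(start = 3, end = 4, dx = 0.6, dy = 0,
                                      dz = 0),
      gap_positions = 6, pdb_id = "EMIT"))
    ch <- relabel_altlocs(parse_structure(fx$path, pdb_id = "EMIT")[[1]])
    index <- build_location_index(ch)
    ctx <- list(chain = ch,
                dihedrals = backbone_dihedrals(ch),
                contacts = chain_contacts(ch, index),
                segments = segment_chain(ch),
                codons = assign_codons(chain_sequence(ch),
                                       make_cds_set(chain_sequence(ch), 2)$cds),
                unp_id = "P00001")
    cache <<- list(ctx = ctx, rows = assemble_rows(ctx))
    cache
  }
})

test_that("row assembly covers every position and flags unmodelled residues", {
  rows <- emit_fixture()$rows
  expect_equal(nrow(rows), 8)          # 7 modelled + 1 gap position
  expect_equal(rows$pdb_idx, 0:7)
  gap <- rows[rows$pdb_idx == 5, ]
  expect_equal(gap$res_icode, "M")
  expect_true(is.na(gap$phi) && is.na(gap$num_altlocs))
  expect_equal(rows$rel_loc[nrow(rows)], 1.0)   # last residue closes (0, 1]
  expect_true(all(rows$rel_loc > 0 & rows$rel_loc <= 1))
  # terminal distances count modelled residues only
  expect_equal(rows$n_terminal_dist[1], 0)
  expect_equal(rows$c_terminal_dist[nrow(rows)], 0)
  expect_equal(rows$n_terminal_dist[7], 5)  # resno 7: six modelled before it
})

test_that("altloc columns carry segment ids, distances and sigmas", {
  rows <- emit_fixture()$rows
  r3 <- rows[rows$pdb_idx == 2, ]  # residue 3, inside the planted segment
  expect_equal(r3$seg_id, 1)
  expect_equal(r3$num_altlocs, 2)
  expect_equal(r3$altlocs_CA, "A;B")
  expect_equal(r3$dist_CA_AB, 0.6)
  expect_equal(r3$sigma_CA_A, round(sqrt(20 / (8 * pi^2)), 3))
  expect_false(is.na(r3$phi_A) || is.na(r3$phi_B))
  expect_equal(r3$contact_types_A, "proximal")
  r1 <- rows[rows$pdb_idx == 0, ]
  expect_true(is.na(r1$seg_id))
  expect_true(is.na(r1$dist_CA_AB))
})

test_that("contact counts equal the rendered list lengths", {
  rows <- emit_fixture()$rows
  count_entries <- function(s) {
    if (is.na(s) || s == "") 0L else length(strsplit(s, ",")[[1]])
  }
  for (r in which(rows$res_icode != "M")) {
    for (sfx in c("", "_A", "_B")) {
      n <- rows[[paste0("contact_count", sfx)]][r]
      if (is.na(n)) next
      got <- count_entries(rows[[paste0("contact_aas", sfx)]][r]) +
        count_entries(rows[[paste0("contact_ooc", sfx)]][r]) +
        count_entries(rows[[paste0("contact_non_aa", sfx)]][r])
      expect_equal(got, n)
    }
  }
})

test_that("the emitted header matches the golden schema byte-for-byte", {
  rows <- emit_fixture()$rows
  path <- tempfile(fileext = ".csv")
  write_data_csv(rows, path)
  header <- readLines(path, n = 1)
  golden <- readLines(system.file("extdata", "golden_data_header.txt",
                                  package = "altlocr"))
  expect_identical(header, paste0("\"", gsub(",", "\",\"", golden), "\""))
  expect_identical(names(read.csv(path, check.names = FALSE)),
                   strsplit(golden, ",")[[1]])
  # metadata schema
  meta <- assemble_metadata_row(emit_fixture()$ctx$chain)
  mpath <- tempfile(fileext = ".csv")
  write_metadata_csv(meta, mpath)
  mgolden <- readLines(system.file("extdata", "golden_metadata_header.txt",
                                   package = "altlocr"))
  expect_identical(names(read.csv(mpath, check.names = FALSE)),
                   strsplit(mgolden, ",")[[1]])
  # wrong schema is refused
  expect_error(write_data_csv(rows[, -2], path), "schema")
})

test_that("CSV round trip preserves values including in-cell delimiters", {
  rows <- emit_fixture()$rows
  path <- tempfile(fileext = ".csv")
  write_data_csv(rows, path)
  back <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(rows))
  expect_equal(back$dist_CA_AB, rows$dist_CA_AB)
  expect_equal(back$phi_A, rows$phi_A, tolerance = 1e-9)
  # in-cell commas inside contact lists survive quoting
  lists <- rows$contact_aas[!is.na(rows$contact_aas) & rows$contact_aas != ""]
  back_lists <- back$contact_aas[!is.na(back$contact_aas) &
                                 back$contact_aas != ""]
  expect_equal(back_lists, lists)
  expect_true(any(grepl(",", lists)))   # the case is actually exercised
  # header-only emission for zero rows
  empty <- rows[0, ]
  write_data_csv(empty, path)
  expect_equal(length(readLines(path)), 1)
})

test_that("metadata rows combine repository fields with computed summaries", {
  transport <- fixture_transport(api_fixture_dir())
  meta <- fetch_chain_metadata("1TST", "A", transport)
  ctx <- emit_fixture()$ctx
  row <- assemble_metadata_row(ctx$chain, meta = meta,
                               segments = ctx$segments, cluster_id = 4L)
  expect_equal(row$num_altloc_segments, 1)
  expect_equal(row$num_altlocs, 2)    # residues harboring altlocs
  expect_equal(row$cluster_id, 4L)
  expect_equal(row$unp_id, "P12345")
  expect_equal(row$seq_len, nchar(meta$entity_sequence))
  expect_equal(names(row), metadata_table_columns())
})
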