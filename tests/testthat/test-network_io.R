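test_that("edge-list parsing builds a validated network and preserves evidence", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("source,target,effect,reference_id",
               "A,B,+1,p1",
               "B,C,-1,p2",
               "A,C,activation,p1"), f)
  net <- parse_interaction_table(f)
  expect_s3_class(net, "regulatory_network")
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$interactions), 3)
  expect_equal(sort(net$interactions$effect), c(-1L, 1L, 1L))
  expect_equal(nrow(net$evidence), 3)

  # TSV dialect, and a repeated row with the same sign is extra evidence
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\teffect\treference_id",
               "A\tB\t1\tp1",
               "A\tB\t1\tp2"), f2)
  net2 <- parse_interaction_table(f2, "edge-list-tsv")
  expect_equal(nrow(net2$interactions), 1)
  expect_equal(nrow(net2$evidence), 2)
})

test_that("parse errors are classed and informative", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("source,sign", "A,B"), f)
  expect_error(parse_interaction_table(f), "missing required column",
               class = "rnm_format_error")

  writeLines(c("source,target,effect", "X,Y,+1", "X,Y,-1"), f)
  err <- tryCatch(parse_interaction_table(f), rnm_conflict_error = identity)
  expect_s3_class(err, "rnm_conflict_error")
  expect_match(conditionMessage(err), "X, Y")

  expect_error(parse_interaction_table(tempfile()), "not found",
               class = "rnm_format_error")
})

test_that("node-name aliases and whitespace are canonicalised", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("source,target,effect",
               " IL-1b ,ACAN,-1",
               "TGF-b,ACAN,+1"), f)
  net <- parse_interaction_table(f)
  expect_setequal(net$nodes$name, c("IL-1β", "TGF-β", "ACAN"))
})

test_that("duplicate-sign conflicts are hard errors in the constructor too", {
  expect_error(
    regulatory_network(c("X", "Y"),
                       data.frame(source = c("X", "X"), target = c("Y", "Y"),
                                  effect = c(1L, -1L))),
    class = "rnm_conflict_error")
  expect_error(
    regulatory_network("A", data.frame(source = "A", target = "Z",
                                       effect = 1L)),
    class = "rnm_validation_error")
})

test_that("degree of connectivity counts undirected incidence", {
  hub <- regulatory_network(
    c("H", paste0("L", 1:5)),
    data.frame(source = "H", target = paste0("L", 1:5), effect = 1L))
  doc <- degree_of_connectivity(hub)
  expect_equal(unname(doc["H"]), 5L)
  expect_true(all(doc[paste0("L", 1:5)] == 1L))
  # handshake identity on loop-free networks
  expect_equal(sum(doc), 2L * nrow(hub$interactions))

  loop <- regulatory_network("A", data.frame(source = "A", target = "A",
                                             effect = 1L))
  expect_equal(unname(degree_of_connectivity(loop)["A"]), 1L)
})

test_that("merge_nodes collapses duplicates, raises sign conflicts, renames cleanly", {
  base <- data.frame(source = c("X", "X"), target = c("A1", "A2"),
                     effect = c(1L, 1L))
  net <- regulatory_network(c("X", "A1", "A2"), base)
  merged <- merge_nodes(net, c("A1", "A2"), "A")
  expect_equal(nrow(merged$interactions), 1)
  expect_equal(merged$interactions$target, "A")
  expect_setequal(merged$nodes$merged_from[[match("A", merged$nodes$name)]],
                  c("A1", "A2"))

  conflicted <- regulatory_network(
    c("X", "A1", "A2"),
    data.frame(source = c("X", "X"), target = c("A1", "A2"),
               effect = c(1L, -1L)))
  expect_error(merge_nodes(conflicted, c("A1", "A2"), "A"),
               class = "rnm_conflict_error")

  # no incident edges: pure rename, edge count unchanged
  lonely <- regulatory_network(c("A1", "A2", "B", "C"),
                               data.frame(source = "B", target = "C",
                                          effect = 1L))
  m2 <- merge_nodes(lonely, c("A1", "A2"), "A")
  expect_equal(nrow(m2$interactions), 1)
  expect_true("A" %in% m2$nodes$name)
})

test_that("remove_nodes drops incident edges and tolerates degenerate cases", {
  chain <- regulatory_network(c("A", "B", "C"),
                              data.frame(source = c("A", "B"),
                                         target = c("B", "C"),
                                         effect = 1L))
  expect_equal(nrow(remove_nodes(chain, "C")$interactions), 1)
  mid <- remove_nodes(chain, "B")
  expect_equal(nrow(mid$nodes), 2)
  expect_equal(nrow(mid$interactions), 0)
  empty <- remove_nodes(chain, c("A", "B", "C"))
  expect_equal(nrow(empty$nodes), 0)
  expect_error(remove_nodes(chain, "Z"), class = "rnm_lookup_error")
})

test_that("corpus_summary counts links and distinct references", {
  net <- regulatory_network(
    c("A", "B", "C"),
    data.frame(source = c("A", "B"), target = c("B", "C"), effect = 1L),
    evidence = data.frame(
      source = c("A", "B"), target = c("B", "C"),
      reference_id = "p1", cell_type = "IVD-NPC", species = "human",
      culture = "2D", pathology = "normal"))
  s <- corpus_summary(net)
  expect_equal(s$totals$links, 2L)
  expect_equal(s$totals$papers, 1L)
  expect_equal(s$by_source$links, 2L)
  # missing annotations fall under n/a, and totals still close
  net2 <- regulatory_network(
    c("A", "B"), data.frame(source = "A", target = "B", effect = 1L),
    evidence = data.frame(source = "A", target = "B", reference_id = "p9"))
  s2 <- corpus_summary(net2)
  expect_equal(s2$by_source$cell_type, "n/a")
  expect_equal(s2$totals$links, 1L)
})

test_that("export/import round-trips preserve nodes, edges and signs", {
  net <- generate_random_network(generator_spec(8, 14, seed = 42))
  key <- function(n) paste(n$interactions$source, n$interactions$target,
                           n$interactions$effect)

  csv <- withr::local_tempfile(fileext = ".csv")
  export_network(net, csv, "edge-list-csv")
  back <- parse_interaction_table(csv)
  expect_setequal(back$nodes$name, net$nodes$name)
  expect_setequal(key(back), key(net))
  expect_equal(stats::setNames(back$nodes$category, back$nodes$name)[net$nodes$name],
               stats::setNames(net$nodes$category, net$nodes$name))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back2 <- import_network(gml, "graphml")
  expect_setequal(back2$nodes$name, net$nodes$name)
  expect_setequal(key(back2), key(net))

  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  back3 <- import_network(sif, "sif")
  expect_setequal(back3$nodes$name, net$nodes$name)
  expect_setequal(key(back3), key(net))

  expect_error(export_network(net, csv, "gexf"), class = "rnm_usage_error")
})

test_that("empty networks export and re-import cleanly", {
  empty <- regulatory_network(character(0), NULL)
  for (fmt in c("edge-list-csv", "graphml", "sif")) {
    f <- withr::local_tempfile()
    export_network(empty, f, fmt)
    back <- if (fmt == "edge-list-csv") parse_interaction_table(f)
            else import_network(f, fmt)
    expect_equal(nrow(back$interactions), 0)
  }
})

test_that("fixture evidence round-trips through the canonical CSV", {
  net <- shared_fixture()
  f <- withr::local_tempfile(fileext = ".csv")
  export_network(net, f, "edge-list-csv")
  back <- parse_interaction_table(f)
  expect_equal(nrow(back$interactions), nrow(net$interactions))
  expect_equal(nrow(back$evidence), nrow(net$evidence))
  expect_equal(corpus_summary(back)$totals, corpus_summary(net)$totals)
})
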