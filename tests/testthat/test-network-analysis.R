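test_that("degrees and roles match hand enumeration", {
  genes <- c("A", "B", "C", "D", "E")
  g <- graph_from_edges(genes, c("A", "A", "B", "C"), c("B", "C", "C", "D"))
  roles <- degrees_and_roles(g)
  rownames(roles) <- roles$gene_id
  expect_equal(roles["A", ]$out_degree, 2)
  expect_equal(roles["A", ]$role, "broadcaster")
  expect_equal(roles["B", ]$role, "mediator")
  expect_equal(unname(unlist(roles["C", c("in_degree", "out_degree")])),
               c(2, 1))
  expect_equal(roles["D", ]$role, "receptor")
  expect_equal(roles["E", ]$role, "isolated")
  expect_equal(unname(unlist(roles["E", c("in_degree", "out_degree")])),
               c(0, 0))
  # conservation: degree sums equal edge counts per direction
  expect_equal(sum(roles$in_degree), 4)
  expect_equal(sum(roles$out_degree), 4)
  expect_equal(nrow(roles), length(genes))
})

test_that("IV edges set has_iv but never contribute to degrees", {
  genes <- c("A", "B")
  g <- graph_from_edges(genes, "A", "B")
  g$edges <- rbind(g$edges,
                   data.frame(from = "A.iv1", to = "A", type = "iv",
                              effect = 0.5, p = 1e-5,
                              oriented_by = "fixed"))
  roles <- degrees_and_roles(g)
  expect_true(roles$has_iv[roles$gene_id == "A"])
  expect_equal(roles$in_degree[roles$gene_id == "A"], 0)
})

test_that("downstream pathways enumerate all simple routes to receptors", {
  genes <- c("A", "B", "C", "D")
  chain <- graph_from_edges(genes[1:3], c("A", "B"), c("B", "C"))
  expect_equal(downstream_pathways(chain, "C"), # receptor: no pathway
               structure(list(), overflow = FALSE))
  paths <- downstream_pathways(chain, "A")
  expect_equal(length(paths), 1)
  expect_equal(paths[[1]], c("A", "B", "C"))
  # diamond A->B->D, A->C->D: exactly two pathways, verified by DFS count
  dia <- graph_from_edges(genes, c("A", "A", "B", "C"), c("B", "C", "D", "D"))
  pd <- downstream_pathways(dia, "A")
  expect_equal(length(pd), 2)
  expect_setequal(vapply(pd, paste, character(1), collapse = "-"),
                  c("A-B-D", "A-C-D"))
  expect_true(all(vapply(pd, function(x) x[length(x)] == "D", logical(1))))
  expect_error(downstream_pathways(chain, "Z"), "not in graph")
})

test_that("modules are the descendant closure of high-out-degree cores", {
  genes <- c(paste0("g", 1:8))
  # core g1 -> g2..g5; g2 -> g6; g6 -> g7 (receptor); g8 isolated
  g <- graph_from_edges(genes,
                        c("g1", "g1", "g1", "g1", "g2", "g6"),
                        c("g2", "g3", "g4", "g5", "g6", "g7"))
  expect_equal(length(find_modules(g, core_min_outdegree = 5)), 0)
  mods <- find_modules(g, core_min_outdegree = 4)
  expect_equal(length(mods), 1)
  m <- mods[[1]]
  expect_equal(m$core, "g1")
  # BFS closure oracle
  expect_setequal(m$members, c("g2", "g3", "g4", "g5", "g6", "g7"))
  expect_setequal(m$boundary, c("g3", "g4", "g5", "g7"))
  expect_equal(m$max_path_length, 3)
  # boundary genes have no out-edges inside the module
  eg <- gene_edges(g)
  expect_false(any(eg$from %in% m$boundary & eg$to %in% c(m$core, m$members)))
})

test_that("odds ratios follow the 2x2 arithmetic with Woolf intervals", {
  mk_roles <- function(deg, flag_names) {
    g <- graph_from_edges(names(deg), character(0), character(0))
    r <- degrees_and_roles(g)
    r$degree <- unname(deg); r$out_degree <- unname(deg)
    r
  }
  # (a,b,c,d) = (10,20,30,15): OR = (10*15)/(20*30) = 0.25
  deg <- setNames(c(rep(3, 30), rep(0, 45)), paste0("x", 1:75))
  flag <- setNames(c(rep(TRUE, 10), rep(FALSE, 20), rep(TRUE, 30),
                     rep(FALSE, 15)), paste0("x", 1:75))
  or <- annotation_degree_odds_ratio(mk_roles(deg), flag,
                                     degree_threshold = 3)
  expect_equal(or$or, 0.25)
  expect_true(or$ci[1] < 0.25 && or$ci[2] > 0.25)
  # balanced independence: OR exactly 1
  deg2 <- setNames(c(rep(4, 50), rep(1, 50)), paste0("y", 1:100))
  flag2 <- setNames(rep(c(TRUE, FALSE), 50), paste0("y", 1:100))
  or2 <- annotation_degree_odds_ratio(mk_roles(deg2), flag2,
                                      degree_threshold = 3)
  expect_equal(or2$or, 1.0)
  # zero cell: continuity-corrected, finite, flagged
  deg3 <- setNames(c(rep(5, 10), rep(0, 10)), paste0("z", 1:20))
  flag3 <- setNames(c(rep(TRUE, 10), rep(c(TRUE, FALSE), 5)),
                    paste0("z", 1:20))
  or3 <- annotation_degree_odds_ratio(mk_roles(deg3), flag3)
  expect_true(or3$corrected && is.finite(or3$or))
  # degenerate margin: diagnostic instead of a number
  or4 <- annotation_degree_odds_ratio(mk_roles(deg3),
                                      setNames(rep(TRUE, 20),
                                               paste0("z", 1:20)))
  expect_true(is.na(or4$or))
})

test_that("high-degree proportions are exact fractions per class", {
  g <- graph_from_edges(paste0("p", 1:40), character(0), character(0))
  roles <- degrees_and_roles(g)
  roles$degree <- c(rep(4, 9), rep(1, 11), rep(4, 6), rep(0, 14))
  flag <- setNames(c(rep(TRUE, 20), rep(FALSE, 20)), roles$gene_id)
  pr <- annotation_degree_proportions(roles, flag, degree_threshold = 4)
  expect_equal(pr$prop_flagged, 9 / 20)
  expect_equal(pr$prop_unflagged, 6 / 20)
  # independent tally oracle
  expect_equal(pr$n_high_flagged,
               sum(roles$degree >= 4 & flag[roles$gene_id]))
  pr2 <- annotation_degree_proportions(roles,
                                       setNames(rep(TRUE, 40),
                                                roles$gene_id))
  expect_true(is.na(pr2$prop_unflagged))
})
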