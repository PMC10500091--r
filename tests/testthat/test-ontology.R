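test_that("a minimal three-term ontology parses with correct depths", {
  obo <- c("[Term]", "id: HP:0000001", "name: root",
           "[Term]", "id: HP:0000002", "name: A", "is_a: HP:0000001 ! root",
           "[Term]", "id: HP:0000003", "name: B", "is_a: HP:0000001 ! root")
  ont <- parse_obo(obo)
  expect_length(ont$ids, 3L)
  expect_identical(ont$root, "HP:0000001")
  expect_identical(unname(ont$depth[c("HP:0000002", "HP:0000003")]), c(1L, 1L))
  expect_identical(ont$name[["HP:0000002"]], "A")
})

test_that("obsolete terms are excluded but resolvable, as are alt_ids", {
  obo <- c("[Term]", "id: HP:0000001", "name: root",
           "[Term]", "id: HP:0000002", "name: live", "is_a: HP:0000001",
           "alt_id: HP:0000099",
           "[Term]", "id: HP:0000003", "name: gone", "is_obsolete: true",
           "replaced_by: HP:0000002")
  ont <- parse_obo(obo)
  expect_false("HP:0000003" %in% ont$ids)
  expect_identical(ont$obsolete[["HP:0000003"]], "HP:0000002")
  expect_identical(resolve_terms(ont, "HP:0000003"), "HP:0000002")
  expect_identical(resolve_terms(ont, "HP:0000099"), "HP:0000002")
  expect_error(resolve_terms(ont, "HP:1234567"), "unknown term ID")
})

test_that("multi-parent terms keep every parent and take the shortest-path depth", {
  ont <- parse_obo(hp_snippet_path())
  expect_setequal(ont$parents[["HP:0200134"]], c("HP:0001250", "HP:0001298"))
  # root -> 118 -> 707 -> 12638 -> {1250, 1298} -> 200134
  expect_identical(ont$depth[["HP:0200134"]], 5L)
  expect_identical(resolve_terms(ont, "HP:0010520"), "HP:0002133")
  expect_identical(resolve_terms(ont, "HP:0001333"), "HP:0000707")

  uneven <- parse_obo(uneven_obo())
  expect_setequal(uneven$parents[["HP:0000006"]],
                  c("HP:0000003", "HP:0000005"))
  expect_identical(uneven$depth[["HP:0000006"]], 2L)
})

test_that("ancestors are reflexive and transitive, with root always present", {
  chain <- parse_obo(chain_obo())
  expect_identical(term_ancestors(chain, "HP:0000001"), "HP:0000001")
  expect_setequal(term_ancestors(chain, "HP:0000003"),
                  c("HP:0000003", "HP:0000002", "HP:0000001"))
  diamond <- parse_obo(diamond_obo())
  expect_setequal(term_ancestors(diamond, "HP:0000004"),
                  c("HP:0000004", "HP:0000002", "HP:0000003", "HP:0000001"))
  expect_error(term_ancestors(chain, "HP:9999999"), "HP:9999999")
})

test_that("ancestor closure matches a brute-force BFS on generated DAGs", {
  brute_ancestors <- function(ont, t) {
    out <- character(0)
    frontier <- t
    while (length(frontier)) {
      out <- union(out, frontier)
      frontier <- setdiff(unique(unlist(ont$parents[frontier],
                                        use.names = FALSE)), out)
    }
    out
  }
  for (seed in 1:6) {
    n <- c(20, 50, 100, 150, 200, 80)[seed]
    ont <- parse_obo(make_ontology(synth_config(seed = seed, n_terms = n)))
    set.seed(seed)
    for (t in sample(ont$ids, 10)) {
      expect_setequal(term_ancestors(ont, t), brute_ancestors(ont, t))
    }
  }
})

test_that("information content follows disease-frequency counting", {
  toy <- ic_toy()
  # 1 of 4 diseases under t1: -ln(1/4)
  expect_equal(unname(toy$ic[["HP:0000003"]]), log(4))
  # p covers D1 and D2: -ln(2/4)
  expect_equal(unname(toy$ic[["HP:0000002"]]), log(2))
  expect_identical(unname(toy$ic[["HP:0000001"]]), 0)

  # every disease annotated to the same term -> ic 0 at that term
  ont <- parse_obo(chain_obo())
  corpus <- annotation_corpus(list(D1 = "HP:0000003", D2 = "HP:0000003"))
  ic <- compute_ic(ont, corpus)
  expect_identical(unname(ic[["HP:0000003"]]), 0)
  # term with no annotated descendant -> infinite sentinel
  expect_identical(unname(ic[["HP:0000004"]]), Inf)
  expect_error(compute_ic(ont, annotation_corpus(list())), "empty")
})

test_that("mica returns the most informative common ancestor with tie-breaks", {
  toy <- ic_toy()
  m <- mica(toy$ontology, toy$ic, "HP:0000003", "HP:0000003")
  expect_identical(m$term, "HP:0000003")
  expect_equal(m$ic, log(4))
  # siblings sharing only the root
  m2 <- mica(toy$ontology, toy$ic, "HP:0000003", "HP:0000005")
  expect_identical(m2$term, "HP:0000001")
  expect_identical(m2$ic, 0)
  # informative shared parent
  m3 <- mica(toy$ontology, toy$ic, "HP:0000003", "HP:0000004")
  expect_identical(m3$term, "HP:0000002")
  expect_equal(m3$ic, log(2))
})

test_that("cyclic and rootless inputs are hard errors naming the problem", {
  cyc <- c("[Term]", "id: HP:0000001", "name: root",
           "[Term]", "id: HP:0000002", "name: A", "is_a: HP:0000001",
           "is_a: HP:0000003",
           "[Term]", "id: HP:0000003", "name: B", "is_a: HP:0000002")
  expect_error(parse_obo(cyc), "cyclic is_a graph")
  rootless <- c("[Term]", "id: HP:0000001", "name: A", "is_a: HP:0000002",
                "[Term]", "id: HP:0000002", "name: B", "is_a: HP:0000001")
  expect_error(parse_obo(rootless), "root|cyclic")
})

test_that("parse -> serialize -> parse preserves terms and edges", {
  for (src in list(parse_obo(hp_snippet_path()),
                   parse_obo(make_ontology(synth_config(seed = 4, n_terms = 120))))) {
    back <- parse_obo(format_obo(src))
    expect_setequal(back$ids, src$ids)
    expect_identical(back$n_edges, src$n_edges)
    expect_identical(back$depth[src$ids], src$depth[src$ids])
  }
})

test_that("HPOA-style annotation files read into a corpus, dropping NOT rows", {
  ont <- parse_obo(chain_obo())
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#comment line",
               "database_id\tdisease_name\tqualifier\thpo_id",
               "D:1\tDisease one\t\tHP:0000003",
               "D:1\tDisease one\tNOT\tHP:0000004",
               "D:2\tDisease two\t\tHP:0000002"), path)
  corpus <- read_hpoa(path, ont)
  expect_identical(corpus$n_diseases, 2L)
  expect_identical(corpus$disease_terms[["D:1"]], "HP:0000003")
  expect_identical(unname(corpus$disease_names[["D:1"]]), "Disease one")
})
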