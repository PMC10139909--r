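test_that("pmid_source reflects Entrez confirmation", {
  expect_equal(pmid_source("123", c("123", "456")), "xml,pmc")
  expect_equal(pmid_source("123", character(0)), "xml")
  expect_equal(pmid_source(NA_character_, c("123")), NA_character_)
})

test_that("select_best applies the threshold lattice", {
  cand <- function(id, space, p, conf = "") {
    data.table::data.table(candidate_id = id, id_space = space,
                           probability = p, confirmations = conf)
  }
  thr <- default_thresholds()
  ## single unconfirmed PMID: needs the 0.997 default
  expect_equal(select_best(cand("1", "pmid", 0.999), thr)$id, "1")
  expect_null(select_best(cand("1", "pmid", 0.996), thr))
  ## confirmation lowers the bar to 0.99
  expect_null(select_best(cand("1", "pmid", 0.95, "icite"), thr))
  expect_equal(select_best(cand("1", "pmid", 0.992, "icite"), thr)$id, "1")
  ## brute-force over the eligibility lattice
  for (p in c(0.90, 0.985, 0.992, 0.9965, 0.998)) {
    for (conf in c("", "icite")) {
      bar <- if (nzchar(conf)) thr$confirmed_pmid else thr$default
      got <- select_best(cand("9", "pmid", p, conf), thr)
      expect_equal(!is.null(got), p >= bar,
                   label = sprintf("p=%g conf=%s", p, conf))
    }
  }
  ## non-PMID displaces the PMID only with a markedly higher probability
  both <- rbind(cand("1", "pmid", 0.998), cand("ADS-X", "ads", 0.9999))
  expect_equal(select_best(both, thr)$id, "ADS-X")
  close_call <- rbind(cand("1", "pmid", 0.998), cand("ADS-X", "ads", 0.9985))
  expect_equal(select_best(close_call, thr)$id, "1")
  expect_null(select_best(cand("x", "pmid", NA_real_), thr))
})

test_that("classify_diff reproduces the seven-value mapping", {
  expect_equal(classify_diff("123", "123", TRUE), "SAME")
  expect_equal(classify_diff(NA, NA, TRUE), "NONE")
  expect_equal(classify_diff("123", NA, TRUE), "INSERT")
  expect_equal(classify_diff("456", "123", TRUE), "SWAP")
  expect_equal(classify_diff(NA, "123", TRUE), "DELETE")
  expect_equal(classify_diff(NA, "123", FALSE), "PMID_XML")
  expect_equal(classify_diff(NA, NA, FALSE), "NONE_XML")
})

test_that("reconcile_ids assigns per-reference results end to end", {
  reg <- make_registry(4) # pmids 10000001..10000004
  cands <- data.table::data.table(
    pmcid = "7000001",
    ref_id = c("B1", "B2", "B2", "B3"),
    candidate_id = c("10000001", "77777777", "10000002", "88888888"),
    id_space = c("pmid", "pmid", "pmid", "pmid"),
    probability = c(0.999, 0.999, 0.5, 0.2),
    confirmations = c("icite;pmc", "", "", ""))
  rec <- reconcile_ids(c("B1", "B2", "B3", "B4"), reg, "7000001",
                       candidates = cands,
                       entrez_cited = c("10000001"))
  rec <- as.data.frame(rec)
  ## B1: matcher agrees with the XML pmid, Entrez confirms
  expect_equal(rec$best_id_diff[1], "SAME")
  expect_equal(rec$intxt_pmid_source[1], "xml,pmc")
  expect_equal(rec$best_source[1], "xml,icite,pmc")
  ## B2: matcher picked a different PMID
  expect_equal(rec$best_id_diff[2], "SWAP")
  expect_equal(rec$best_id[2], "77777777")
  expect_equal(rec$best_source[2], "matcher")
  ## B3: cross-checked, nothing eligible, but XML pmid exists
  expect_equal(rec$best_id_diff[3], "DELETE")
  expect_true(is.na(rec$best_id[3]))
  ## B4: never cross-checked
  expect_equal(rec$best_id_diff[4], "PMID_XML")
  expect_equal(rec$best_id[4], "10000004")
  expect_equal(rec$best_source[4], "xml")
  ## invariant: best_id absent exactly for NONE/DELETE/NONE_XML
  expect_equal(is.na(rec$best_id),
               rec$best_id_diff %in% c("NONE", "DELETE", "NONE_XML"))
})

test_that("without external inputs reconciliation degenerates to XML values", {
  art <- generate_article(dialect_config(n_refs = 8, seed = 31,
                                         untagged_pmid_rate = 0.4))
  rec <- process_article(art$xml)$records
  citing <- rec[!is.na(rec$intxt_id)]
  expect_true(all(citing$best_id_diff %in% c("PMID_XML", "NONE_XML")))
  tagged <- !is.na(citing$intxt_pmid)
  expect_equal(citing$best_id[tagged], citing$intxt_pmid[tagged])
  expect_true(all(is.na(citing$best_id[!tagged])))
  ## all citations of one reference share identical reconciliation fields
  by_ref <- split(citing, citing$intxt_id)
  for (g in by_ref) {
    expect_equal(length(unique(paste(g$best_id, g$best_source,
                                     g$best_id_diff))), 1L)
  }
})
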