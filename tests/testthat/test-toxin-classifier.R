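test_that("keyword selection is a case-insensitive substring match", {
  ann <- data.frame(unigene_id = c("u1", "u2", "u3"),
                    text = c("putative Serine Protease 12",
                             "ribosomal protein L3", "CAP superfamily"))
  expect_equal(select_by_keywords(ann), c("u1", "u3"))
  expect_equal(select_by_keywords(ann[2, , drop = FALSE]), character(0))
  expect_equal(length(toxin_keywords()), 9L)
})

test_that("dual-database filter truth table holds exactly", {
  expect_true(dual_db_filter(50, 40, FALSE))   # toxin wins
  expect_false(dual_db_filter(40, 50, FALSE))  # animal wins, not venomous
  expect_true(dual_db_filter(40, 50, TRUE))    # venomous exception
  expect_true(dual_db_filter(40, 40, FALSE))   # tie kept
  expect_true(dual_db_filter(40, NULL))        # no animal hit
  expect_true(dual_db_filter(40, NA))
})

test_that("completeness tagging partitions the four cases", {
  expect_equal(tag_completeness(TRUE, TRUE, 0, 100, 100), "Full")
  expect_equal(tag_completeness(FALSE, TRUE, 50, 100, 100), "NTE")
  expect_equal(tag_completeness(TRUE, FALSE, 0, 40, 100), "CTE")
  expect_equal(tag_completeness(FALSE, FALSE, 50, 40, 100), "NC")
  # margin boundary: s_start must be strictly below the margin
  expect_equal(tag_completeness(TRUE, TRUE, 20, 100, 100, margin = 20),
               "NTE")
  expect_equal(tag_completeness(TRUE, TRUE, 19, 100, 100, margin = 20),
               "Full")
})

test_that("display names parse back to their fields", {
  for (nm in list(list("ctg0001", "kazal", "Full", FALSE),
                  list("ctg0002+ctg0003", "peptidase_S1", "Full", TRUE),
                  list("u9", "CAP", "NC", FALSE))) {
    dn <- venomscreen:::.display_name(nm[[1]], nm[[2]], nm[[3]], nm[[4]])
    p <- parse_display_name(dn)
    expect_equal(p$unigene_id, nm[[1]])
    expect_equal(p$toxin_class, nm[[2]])
    expect_equal(p$completeness, nm[[3]])
    expect_equal(p$joined, nm[[4]])
  }
})

make_fragment_pair <- function(P, a_end, b_start, mutate_overlap = 0) {
  db <- protein_db("subj", P, toxin_class = "fam")
  fragA <- substring(P, 1, a_end)
  fragB <- substring(P, b_start + 1)
  if (mutate_overlap > 0) {
    ov <- (b_start + 1):a_end
    idx <- ov[seq_len(ceiling(length(ov) * mutate_overlap))]
    bb <- strsplit(fragB, "")[[1]]
    rel <- idx - b_start
    bb[rel] <- ifelse(bb[rel] == "A", "G", "A")
    fragB <- paste(bb, collapse = "")
  }
  row <- function(id, prot, s_start, s_end, comp, met, stop) {
    data.frame(unigene_id = id, protein = prot, toxin_class = "fam",
               toxin_subject = "subj", s_start = s_start, s_end = s_end,
               completeness = comp, has_start_met = met, has_stop = stop,
               display_name = paste0(id, "_fam_", comp), joined = FALSE,
               stringsAsFactors = FALSE)
  }
  list(db = db,
       c1 = row("u1", fragA, 0L, a_end, "CTE", TRUE, FALSE),
       c2 = row("u2", fragB, b_start, nchar(P), "NTE", FALSE, TRUE))
}

test_that("overlapping fragments merge into a Join gene model", {
  set.seed(30)
  P <- paste0("M", random_peptide(89))        # 90 residues
  pr <- make_fragment_pair(P, a_end = 60, b_start = 40)  # overlap 20
  m <- merge_fragments(pr$c1, pr$c2, pr$db)
  expect_false(is.null(m))
  expect_equal(nchar(m$protein), 90L)          # 60 + 50 - 20
  expect_equal(m$protein, P)
  expect_true(m$joined)
  expect_match(m$display_name, "_Join$")
  expect_equal(m$completeness, "Full")

  # overlap below the threshold
  pr10 <- make_fragment_pair(P, a_end = 50, b_start = 40)
  expect_null(merge_fragments(pr10$c1, pr10$c2, pr10$db))
  # sufficient overlap but low identity
  prbad <- make_fragment_pair(P, a_end = 60, b_start = 40,
                              mutate_overlap = 0.5)
  expect_null(merge_fragments(prbad$c1, prbad$c2, prbad$db))
  # different subjects or classes never merge
  c2b <- pr$c2; c2b$toxin_subject <- "other"
  expect_null(merge_fragments(pr$c1, c2b, pr$db))
  # two full-length near-identical paralogs never merge
  cf1 <- pr$c1; cf1$completeness <- "Full"
  cf2 <- pr$c2; cf2$completeness <- "Full"
  expect_null(merge_fragments(cf1, cf2, pr$db))
})

test_that("classification recovers the planted universe of the small bundle", {
  b <- tiny_bundle()
  cand <- tiny_candidates()
  truth <- b$truth
  tox <- truth[truth$class == "toxin", ]
  got <- unlist(strsplit(cand$unigene_id, "+", fixed = TRUE))
  expect_setequal(intersect(tox$contig_id, got), tox$contig_id)
  # the probe arrives through the reciprocal search
  probe <- tox$contig_id[tox$expected_provenance == "reciprocal"]
  expect_equal(cand$provenance[cand$unigene_id %in% probe],
               rep("reciprocal", length(probe)))
  # toxin-like housekeeping decoys are filtered by the dual filter
  hk <- truth$contig_id[truth$class == "housekeeping"]
  expect_equal(sum(hk %in% got), 0L)
  # completeness tags match planted truth for unjoined candidates
  un <- cand[!cand$joined, ]
  mm <- match(un$unigene_id, tox$contig_id)
  ok <- !is.na(mm)
  expect_equal(un$completeness[ok], tox$completeness[mm][ok])
  # split pair merged
  expect_equal(sum(cand$joined), 1L)
  # classes match truth
  expect_equal(un$toxin_class[ok], tox$toxin_class[mm][ok])
  # every retained candidate satisfies the E-value cutoff
  expect_true(all(cand$toxin_evalue <= 1e-5))
  # venomous-taxon exception exercised: CAP candidates kept despite a
  # closer venomous animal hit
  cap <- cand[cand$toxin_class == "CAP", ]
  expect_true(nrow(cap) > 0 && any(cap$animal_is_venomous))
  expect_true(all(!is.na(cap$animal_bit)))
})

test_that("classification is deterministic and errors on inconsistent input", {
  b <- tiny_bundle()
  c1 <- tiny_candidates()
  c2 <- classify_transcriptome(b$transcriptome, b$counts, b$annotations,
                               b$toxin_db, b$animal_db)
  expect_identical(c1, c2)
  bad <- rbind(b$counts, data.frame(contig_id = "ghost", length_bp = 100,
                                    count = 1))
  expect_error(classify_transcriptome(b$transcriptome, bad, b$annotations,
                                      b$toxin_db, b$animal_db), "ghost")
})

test_that("reciprocal expansion reaches a fixpoint", {
  b <- tiny_bundle()
  cand <- tiny_candidates()
  cfg <- classify_config()
  tox_index <- db_search_index(b$toxin_db)
  an_index <- db_search_index(b$animal_db)
  again <- reciprocal_expand(cand, b$transcriptome, tox_index, an_index, cfg)
  expect_equal(sort(again$unigene_id), sort(cand$unigene_id))
})
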