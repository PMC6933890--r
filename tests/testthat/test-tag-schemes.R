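train_mentions_fixture <- function() {
  data.frame(
    etype = "FamilyMember",
    fm = c("Mother", "Cousin", "Cousin", "Aunt", "Sibling"),
    sf = c("NA", "Maternal", "NA", "Paternal", "NA"),
    stringsAsFactors = FALSE)
}

test_that("the three schemes carry the expected inventories", {
  expect_identical(standard_scheme()$labels,
                   c("B-FM", "I-FM", "B-Ob", "I-Ob", "O"))
  sc <- side_scheme(c("Cousin", "Aunt"))
  expect_length(sc$labels, 11)
  expect_true(all(c("B-FM_NA", "B-FM_SIDE_NA", "B-FM_SIDE_Paternal",
                    "B-FM_SIDE_Maternal", "B-Ob", "O") %in% sc$labels))
  # relation-side inventory is data driven: pairs observed x {B, I} + Ob + O
  rs <- build_relation_side_scheme(train_mentions_fixture())
  expect_length(rs$labels, 5 * 2 + 3)  # fixture has 5 distinct (fm, sf) pairs
  expect_true("B-FM_Cousin_Maternal" %in% rs$labels)
  # two observed pairs give 2 x 2 + 3 = 7 labels
  two <- data.frame(etype = "FamilyMember", fm = c("Mother", "Cousin"),
                    sf = c("NA", "Maternal"), stringsAsFactors = FALSE)
  expect_length(build_relation_side_scheme(two)$labels, 7)
  # duplicates collapse; empty training set warns and leaves only Ob/O
  rs2 <- build_relation_side_scheme(rbind(train_mentions_fixture(),
                                          train_mentions_fixture()))
  expect_identical(rs$labels, rs2$labels)
  expect_warning(rs0 <- build_relation_side_scheme(train_mentions_fixture()[0, ]),
                 "empty")
  expect_length(rs0$labels, 3)
})

test_that("the cousin mention encodes differently under each scheme", {
  m <- data.frame(first = 1L, last = 1L, etype = "FamilyMember",
                  fm = "Cousin", sf = "Maternal", stringsAsFactors = FALSE)
  side <- build_side_scheme(train_mentions_fixture())
  rel <- build_relation_side_scheme(train_mentions_fixture())
  expect_equal(encode_labels(m, 1, standard_scheme()), "B-FM")
  expect_equal(encode_labels(m, 1, side), "B-FM_SIDE_Maternal")
  expect_equal(encode_labels(m, 1, rel), "B-FM_Cousin_Maternal")
  # members never observed with a side encode as FM_NA
  mo <- data.frame(first = 1L, last = 1L, etype = "FamilyMember",
                   fm = "Mother", sf = "NA", stringsAsFactors = FALSE)
  expect_equal(encode_labels(mo, 1, side), "B-FM_NA")
  expect_equal(encode_labels(NULL, 3, side), c("O", "O", "O"))
})

test_that("encode rejects overlaps and out-of-inventory pairs", {
  side <- build_side_scheme(train_mentions_fixture())
  overlap <- data.frame(first = c(1L, 2L), last = c(2L, 3L),
                        etype = "FamilyMember", fm = "Mother", sf = "NA",
                        stringsAsFactors = FALSE)
  expect_error(encode_labels(overlap, 3, side), "overlapping")
  rel <- build_relation_side_scheme(train_mentions_fixture())
  unseen <- data.frame(first = 1L, last = 1L, etype = "FamilyMember",
                       fm = "Uncle", sf = "Paternal", stringsAsFactors = FALSE)
  expect_error(encode_labels(unseen, 1, rel), "inventory")
})

test_that("decoding recovers spans and tag-borne properties", {
  side <- build_side_scheme(train_mentions_fixture())
  rel <- build_relation_side_scheme(train_mentions_fixture())
  d1 <- decode_labels("B-FM_SIDE_Maternal", side)
  expect_equal(d1$etype, "FamilyMember")
  expect_equal(d1$sf, "Maternal")
  expect_true(is.na(d1$fm))
  d2 <- decode_labels(c("B-FM_Cousin_Maternal", "O", "B-Ob", "I-Ob"), rel)
  expect_equal(d2$fm[1], "Cousin")
  expect_equal(d2$sf[1], "Maternal")
  expect_equal(d2[2, c("first", "last")], data.frame(first = 3L, last = 4L),
               ignore_attr = TRUE)
  expect_equal(nrow(decode_labels(c("O", "O", "O"), side)), 0)
  # FM_NA and FM_SIDE_NA both decode to side NA
  expect_equal(decode_labels("B-FM_NA", side)$sf, "NA")
  expect_equal(decode_labels("B-FM_SIDE_NA", side)$sf, "NA")
})

test_that("IOB2 repair rewrites orphan continuations and is idempotent", {
  expect_equal(repair_iob2(c("O", "I-FM")), c("O", "B-FM"))
  expect_equal(repair_iob2(c("B-Ob", "I-FM")), c("B-Ob", "B-FM"))
  expect_equal(repair_iob2(c("B-FM", "I-FM")), c("B-FM", "I-FM"))
  set.seed(41)
  labs <- c("O", "B-FM", "I-FM", "B-Ob", "I-Ob")
  for (i in 1:25) {
    x <- sample(labs, 8, replace = TRUE)
    r <- repair_iob2(x)
    expect_true(iob2_valid(r))
    expect_identical(repair_iob2(r), r)
  }
})

test_that("encode/decode round-trips over randomized mention sets", {
  set.seed(7)
  base <- family_base_names()
  schemes <- list(standard = standard_scheme())
  # build data-driven schemes from a pool guaranteeing full coverage
  pool <- do.call(rbind, lapply(1:200, function(i) random_mention_set(10)))
  schemes$side <- build_side_scheme(pool)
  schemes$relation_side <- build_relation_side_scheme(expand.grid(
    etype = "FamilyMember", fm = base$name,
    sf = c("NA", "Maternal", "Paternal"), stringsAsFactors = FALSE))
  for (i in 1:200) {
    n <- sample(1:12, 1)
    m <- random_mention_set(n)
    for (nm in names(schemes)) {
      sc <- schemes[[nm]]
      dec <- decode_labels(encode_labels(m, n, sc), sc)
      expect_equal(nrow(dec), nrow(m))
      if (nrow(m) == 0) next
      m_ord <- m[order(m$first), ]
      expect_equal(dec$first, m_ord$first)
      expect_equal(dec$last, m_ord$last)
      expect_equal(dec$etype, m_ord$etype)
      fam <- dec$etype == "FamilyMember"
      if (nm == "side") {
        expected_sf <- ifelse(m_ord$fm %in% sc$side_eligible, m_ord$sf, "NA")
        expect_equal(dec$sf[fam], expected_sf[fam])
      } else if (nm == "relation_side") {
        expect_equal(dec$fm[fam], m_ord$fm[fam])
        expect_equal(dec$sf[fam], m_ord$sf[fam])
      }
    }
  }
})
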