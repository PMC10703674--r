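test_that("the cascade hand-traces correctly on single fragments", {
  fx <- partner_fixture()
  agg <- function(code, r_max) {
    structure(list(segment_id = 1L, center_node = 1L, R_nm = 25000,
                   mean_vector = c(code, 0, 0, 0), n_nodes = 3L,
                   r_max_nm = r_max),
              class = "segclr_aggregate")
  }
  # rule 1: short fragment wins over everything
  r <- classify_fragment(agg(2, 1000), fx$coarse, fx$fine, fx$groups)
  expect_equal(r$label, "UNC")
  expect_equal(r$stage, "short_fragment")
  # rule 2: coarse u = 0.5 > 0.45
  r <- classify_fragment(agg(1, 9000), fx$coarse, fx$fine, fx$groups)
  expect_equal(r$label, "UNC")
  expect_equal(r$stage, "uncertain_coarse")
  # rule 3: glia
  r <- classify_fragment(agg(3, 9000), fx$coarse, fx$fine, fx$groups)
  expect_equal(r$label, "UNC")
  expect_equal(r$stage, "glia")
  # rule 4: inhibitory, subtype confident -> best inhibitory subtype
  r <- classify_fragment(agg(5, 9000), fx$coarse, fx$fine, fx$groups)
  expect_equal(r$label, "basket")
  # rule 4 fallback
  r <- classify_fragment(agg(4, 9000), fx$coarse, fx$fine, fx$groups)
  expect_equal(r$label, "I-UNC")
  # rule 5: TC 0.20 < pyramidal sum 0.70 -> best pyramidal subtype
  r <- classify_fragment(agg(6, 9000), fx$coarse, fx$fine, fx$groups)
  expect_equal(r$label, "p23")
  expect_equal(r$stage, "pyramidal_subtype")
})

test_that("thalamocortical rule fires exactly on the probability
          comparison", {
  fx <- partner_fixture()
  agg <- structure(list(segment_id = 1L, center_node = 1L, R_nm = 25000,
                        mean_vector = c(3, 0, 0, 0), n_nodes = 3L,
                        r_max_nm = 9000),
                   class = "segclr_aggregate")
  # code 3 in the fine table: u 0.01, TC 0.40 vs p23+p4 = 0.50 -> pyramidal
  coarse_exc <- stub_model(tibble::tibble(
    code = 3, pred_class = "excitatory", u = 0.1,
    excitatory = 0.8, inhibitory = 0.1, glia = 0.1))
  r <- classify_fragment(agg, coarse_exc, fx$fine, fx$groups)
  expect_equal(r$label, "p23")
  # tip the balance: TC 0.40 vs pyramidal sum 0.35 -> thalamocortical
  fine2 <- stub_model(tibble::tibble(
    code = 3, pred_class = "p23", u = 0.01, basket = 0.1,
    martinotti = 0.15, thalamocortical = 0.40, p23 = 0.20, p4 = 0.15))
  r2 <- classify_fragment(agg, coarse_exc, fine2, fx$groups)
  expect_equal(r2$label, "thalamocortical")
})

test_that("synapse typing preserves rows and reports the filter stages", {
  fx <- partner_fixture()
  # pre segments 101-110: 1-3 short (2 nodes), 4-10 long (11 nodes)
  pre_codes <- c(2, 2, 2, 1, 3, 4, 5, 2, 6, 6)
  segs <- list()
  store <- NULL
  for (i in 1:10) {
    n_nodes <- if (i <= 3) 2 else 11
    fs <- fixture_segment(100L + i, pre_codes[i], n_nodes)
    segs[[as.character(100L + i)]] <- fs$skel
    store <- dplyr::bind_rows(store, fs$store)
  }
  # post segments 201-210: all long and confidently excitatory-pyramidal
  for (i in 1:10) {
    fs <- fixture_segment(200L + i, 6, 11, y_nm = 3000)
    segs[[as.character(200L + i)]] <- fs$skel
    store <- dplyr::bind_rows(store, fs$store)
  }
  synapses <- tibble::tibble(synapse_id = 1:10,
                             pre_segment_id = 101:110,
                             post_segment_id = 201:210,
                             x = 500, y = 1500, z = 0)
  out <- type_synapses(synapses, store, segs, fx$coarse, fx$fine,
                       fx$groups)
  typed <- out$typed
  expect_equal(nrow(typed), 10)  # conservation: no synapse dropped
  expect_equal(typed$pre_label[1:3], rep("UNC", 3))
  expect_equal(typed$pre_stage[1:3], rep("short_fragment", 3))
  expect_equal(typed$pre_label[4:10],
               c("UNC", "UNC", "I-UNC", "basket", "P-UNC", "p23", "p23"))
  expect_equal(typed$pre_stage[4:5], c("uncertain_coarse", "glia"))
  expect_true(all(typed$post_label == "p23"))
  # filter report: 30% of pre fragments fail the short filter
  rep_pre <- out$report[out$report$side == "pre", ]
  expect_equal(rep_pre$fraction[rep_pre$stage == "short_fragment"], 0.3)
  expect_equal(sum(rep_pre$n), 10)
  rep_post <- out$report[out$report$side == "post", ]
  expect_equal(sum(rep_post$n), 10)
  # a segment without embeddings becomes UNC / no_embedding
  syn2 <- tibble::tibble(synapse_id = 1L, pre_segment_id = 999L,
                         post_segment_id = 201L, x = 500, y = 1500, z = 0)
  out2 <- type_synapses(syn2, store, segs, fx$coarse, fx$fine, fx$groups)
  expect_equal(out2$typed$pre_label, "UNC")
  expect_equal(out2$typed$pre_stage, "no_embedding")
  expect_error(type_synapses(synapses[0, ], store, segs, fx$coarse,
                             fx$fine, fx$groups), "empty")
})

test_that("axonal sorting bins by soma distance and summarizes across
          cells", {
  # one cell: chain of 51 nodes 1,000 nm apart (0..50 um), soma at node 1
  fs <- fixture_segment(301L, 1, 51)
  skel <- fs$skel
  soma <- skel$nodes$node_id[1]
  typed <- tibble::tibble(
    synapse_id = 1:3, pre_segment_id = 301L, post_segment_id = 1:3,
    x = c(5000, 25000, 45000), y = 0, z = 0,
    post_label = c("p23", "basket", "thalamocortical"))
  lg <- c(p23 = "excitatory", thalamocortical = "excitatory",
          basket = "inhibitory")
  srt <- axonal_sorting(typed, list("301" = skel),
                        c("301" = soma), lg)
  expect_equal(srt$per_cell$bin, c(0, 1, 2))
  expect_equal(srt$per_cell$exc_ratio, c(1, 0, 1))
  # single-cell bins report s.e.m. 0 with n = 1
  expect_true(all(srt$summary$sem == 0))
  expect_true(all(srt$summary$n_cells == 1))
  # all-excitatory partners give ratio 1 in every occupied bin
  typed2 <- typed
  typed2$post_label <- "p23"
  srt2 <- axonal_sorting(typed2, list("301" = skel), c("301" = soma), lg)
  expect_true(all(srt2$per_cell$exc_ratio == 1))
  # uncertain labels are ignored entirely
  typed3 <- dplyr::bind_rows(
    typed, tibble::tibble(synapse_id = 4, pre_segment_id = 301L,
                          post_segment_id = 4, x = 5200, y = 0, z = 0,
                          post_label = "UNC"))
  srt3 <- axonal_sorting(typed3, list("301" = skel), c("301" = soma), lg)
  expect_equal(srt3$per_cell$n_syn, srt$per_cell$n_syn)
  # two cells sharing a bin: mean and s.e.m. across cells
  fsb <- fixture_segment(302L, 1, 51)
  typed4 <- dplyr::bind_rows(
    typed,
    tibble::tibble(synapse_id = 5:6, pre_segment_id = 302L,
                   post_segment_id = 5:6, x = c(5000, 6000), y = 0, z = 0,
                   post_label = c("p23", "basket")))
  srt4 <- axonal_sorting(typed4,
                         list("301" = skel, "302" = fsb$skel),
                         c("301" = soma, "302" = fsb$skel$nodes$node_id[1]),
                         lg)
  b0 <- srt4$summary[srt4$summary$bin == 0, ]
  expect_equal(b0$n_cells, 2)
  expect_equal(b0$mean_exc_ratio, mean(c(1, 0.5)))
  expect_equal(b0$sem, sd(c(1, 0.5)) / sqrt(2))
})
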