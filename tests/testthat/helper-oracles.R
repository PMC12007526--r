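# independent brute-force sums of squares for a balanced 2-within-factor
# mixed design, straight from cell and marginal means
brute_force_mixed_anova <- function(d) {
  ag <- function(f) {
    m <- aggregate(d$y, d[f], mean)
    names(m)[ncol(m)] <- "m"
    m
  }
  M <- mean(d$y)
  S <- length(unique(d$id))
  sub <- unique(d[, c("id", "group")])
  n_g <- table(sub$group)
  b <- length(unique(d$hemisphere)); cc <- length(unique(d$condition))
  m_s <- ag("id"); m_g <- ag("group")
  m_b <- ag("hemisphere"); m_c <- ag("condition")
  m_gb <- ag(c("group", "hemisphere")); m_gc <- ag(c("group", "condition"))
  m_bc <- ag(c("hemisphere", "condition"))
  m_gbc <- ag(c("group", "hemisphere", "condition"))
  m_sb <- ag(c("id", "hemisphere")); m_sc <- ag(c("id", "condition"))
  look <- function(tab, ...) {
    key <- interaction(...)
    tkey <- interaction(tab[, -ncol(tab), drop = FALSE])
    tab$m[match(key, tkey)]
  }
  SS_A <- b * cc * sum(n_g * (m_g$m - M)^2)
  SS_S <- b * cc * sum((m_s$m - look(m_g, sub$group[match(m_s$id, sub$id)]))^2)
  SS_B <- S * cc * sum((m_b$m - M)^2)
  SS_AB <- cc * sum(n_g[m_gb$group] * (m_gb$m - look(m_g, m_gb$group) -
                                         look(m_b, m_gb$hemisphere) + M)^2)
  strat_b <- cc * sum((m_sb$m - look(m_s, m_sb$id))^2)
  SS_eB <- strat_b - SS_B - SS_AB
  SS_C <- S * b * sum((m_c$m - M)^2)
  SS_AC <- b * sum(n_g[m_gc$group] * (m_gc$m - look(m_g, m_gc$group) -
                                        look(m_c, m_gc$condition) + M)^2)
  strat_c <- b * sum((m_sc$m - look(m_s, m_sc$id))^2)
  SS_eC <- strat_c - SS_C - SS_AC
  SS_BC <- S * sum((m_bc$m - look(m_b, m_bc$hemisphere) -
                      look(m_c, m_bc$condition) + M)^2)
  SS_ABC <- sum(n_g[m_gbc$group] *
                  (m_gbc$m - look(m_gb, m_gbc$group, m_gbc$hemisphere) -
                     look(m_gc, m_gbc$group, m_gbc$condition) -
                     look(m_bc, m_gbc$hemisphere, m_gbc$condition) +
                     look(m_g, m_gbc$group) + look(m_b, m_gbc$hemisphere) +
                     look(m_c, m_gbc$condition) - M)^2)
  SS_tot <- sum((d$y - M)^2)
  SS_eBC <- SS_tot - SS_A - SS_S - SS_B - SS_AB - SS_eB - SS_C - SS_AC -
    SS_eC - SS_BC - SS_ABC
  df_e <- c(S - 2, S - 2, S - 2, S - 2, S - 2, S - 2, S - 2)
  eff <- data.frame(
    effect = c("A", "B", "A:B", "C", "A:C", "B:C", "A:B:C"),
    ss = c(SS_A, SS_B, SS_AB, SS_C, SS_AC, SS_BC, SS_ABC),
    df1 = 1,
    err = c(SS_S, SS_eB, SS_eB, SS_eC, SS_eC, SS_eBC, SS_eBC),
    df2 = S - 2)
  eff$F <- (eff$ss / eff$df1) / (eff$err / eff$df2)
  eff$p <- pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE)
  eff
}
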