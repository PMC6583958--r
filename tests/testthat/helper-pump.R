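# Shared fixtures: standard configurations and the printed specification
# table of the dosing unit (flows in mL/min to 4 decimals; the published
# sheet uses r_S = 150 deg/mm).

cfg_10ml <- function(n_gearboxes = 2, r_S = 90, n_syringes = 1) {
  pump_config(standard_syringe("10 mL"), gear_train(n_gearboxes),
              r_S = r_S, n_syringes = n_syringes)
}

cfg_1ml <- function(n_gearboxes = 2, r_S = 90) {
  pump_config(standard_syringe("1 mL"), gear_train(n_gearboxes), r_S = r_S)
}

# Published specification sheet: rows = gearbox count 0/1/2, columns =
# syringe sizes 50/20/10/1 mL (l_V 1.8/5/8/57 mm/mL).
table1_vmax <- rbind(
  c(210.3556, 75.7280, 47.3300, 6.6428),
  c(8.7648, 3.1553, 1.9721, 0.2768),
  c(0.3652, 0.1315, 0.0822, 0.0115))
table1_vmin <- rbind(
  c(12.4212, 4.4716, 2.7948, 0.3922),
  c(0.5175, 0.1863, 0.1164, 0.0163),
  c(0.0216, 0.0078, 0.0048, 0.0007))
table1_syringes <- c("50 mL", "20 mL", "10 mL", "1 mL")
table1_vtotal <- c(19.4444, 7.0000, 4.3750, 0.6034)  # 1 mL cell implies l_V = 58

# The growth-rate settings actually run on the unit: mu_set (h^-1),
# initial biomass (mg/mL), feed concentration (mg/mL), syringe type.
growth_settings <- data.frame(
  mu_set = c(0.1, 0.3, 0.35, 0.4),
  c_X0 = c(0.03, 0.05, 0.05, 0.04),
  c_S0 = c(36, 18, 18, 36),
  syringe = c("1 mL", "10 mL", "10 mL", "10 mL"),
  stringsAsFactors = FALSE)

table2_config <- function(i) {
  pump_config(standard_syringe(growth_settings$syringe[i]), gear_train(2),
              r_S = 90)
}

table2_spec <- function(i) {
  fedbatch_spec(growth_settings$mu_set[i], V_R = 50,
                c_X0 = growth_settings$c_X0[i], Y_XS = 0.35,
                c_S0 = growth_settings$c_S0[i])
}
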