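# Shared fixtures: the calibrated parameter set and the two typical
# exposure protocols (2-week constant 20 mM; 2-week 5<->20 mM square wave),
# each with a 10-week normalization tail.

table1 <- ros_params()

cg20_2w <- function(ng_h = 1680) make_cg(20, 336, ng_duration_h = ng_h)
og520_2w <- function(ng_h = 1680) make_og(5, 20, 24, 336, ng_duration_h = ng_h)

# generating values of the calibrated population model, for recovery checks
pop_truth <- c(ktu_ROS = 0.0316, ktu_AD = 0.00714, a_gluros = 0.364,
               EC50_ad = 6.142, omega_ktu_ROS = 1.145,
               omega_a_gluros = 0.936, b = 0.09932)
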