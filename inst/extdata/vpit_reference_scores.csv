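metric,characteristic,family,phase,auc,icc,srd_pct,eta,model_quality_pass,all_criteria_flag
jerk_tp,mov_smoothness_tp,smoothness,transport,0.80,0.69,23.10,-4.41,TRUE,FALSE
log_jerk_tp,mov_smoothness_tp,smoothness,transport,0.78,0.74,26.11,-4.82,TRUE,TRUE
sparc_tp,mov_smoothness_tp,smoothness,transport,0.84,0.83,23.78,-7.16,FALSE,FALSE
num_velocity_peaks_tp,mov_smoothness_tp,smoothness,transport,0.82,0.79,21.30,-6.36,FALSE,FALSE
dist_to_max_velocity_tp,mov_smoothness_tp,smoothness,transport,0.44,0.74,33.64,2.42,FALSE,FALSE
time_to_max_velocity_tp,mov_smoothness_tp,smoothness,transport,0.45,0.78,28.70,3.93,FALSE,FALSE
jerk_rt,mov_smoothness_rt,smoothness,return,0.84,0.68,20.83,-4.70,TRUE,FALSE
log_jerk_rt,mov_smoothness_rt,smoothness,return,0.73,0.75,25.33,-6.08,TRUE,TRUE
sparc_rt,mov_smoothness_rt,smoothness,return,0.71,0.76,28.93,-1.57,TRUE,TRUE
num_velocity_peaks_rt,mov_smoothness_rt,smoothness,return,0.76,0.70,23.27,-3.28,FALSE,TRUE
dist_to_max_velocity_rt,mov_smoothness_rt,smoothness,return,0.43,0.65,41.39,3.67,TRUE,FALSE
time_to_max_velocity_rt,mov_smoothness_rt,smoothness,return,0.48,0.73,33.99,2.43,TRUE,FALSE
path_length_ratio_tp,mov_efficiency_tp,efficiency,transport,0.89,0.76,24.24,-2.17,TRUE,TRUE
throughput_tp,mov_efficiency_tp,efficiency,transport,0.92,0.81,24.07,-12.18,FALSE,FALSE
path_length_ratio_rt,mov_efficiency_rt,efficiency,return,0.83,0.79,17.30,-3.61,TRUE,TRUE
throughput_rt,mov_efficiency_rt,efficiency,return,0.90,0.78,27.43,-13.21,TRUE,FALSE
trajectory_error_mean_tp,mov_curvature_tp,curvature,transport,0.55,0.86,17.14,-0.60,TRUE,FALSE
trajectory_error_max_tp,mov_curvature_tp,curvature,transport,0.57,0.86,15.84,-0.37,TRUE,FALSE
initial_mov_angle_tp_t1,mov_curvature_tp,curvature,transport,0.67,0.90,13.56,-1.50,FALSE,FALSE
initial_mov_angle_tp_t2,mov_curvature_tp,curvature,transport,0.67,0.90,13.29,-1.52,FALSE,FALSE
initial_mov_angle_tp_t3,mov_curvature_tp,curvature,transport,0.61,0.88,14.37,-2.06,TRUE,FALSE
trajectory_error_mean_rt,mov_curvature_rt,curvature,return,0.56,0.84,20.00,1.24,TRUE,FALSE
trajectory_error_max_rt,mov_curvature_rt,curvature,return,0.55,0.84,18.58,1.22,TRUE,FALSE
initial_mov_angle_rt_t1,mov_curvature_rt,curvature,return,0.51,0.75,33.90,3.18,TRUE,FALSE
initial_mov_angle_rt_t2,mov_curvature_rt,curvature,return,0.51,0.71,28.65,2.92,TRUE,FALSE
initial_mov_angle_rt_t3,mov_curvature_rt,curvature,return,0.60,0.79,23.99,1.53,TRUE,FALSE
velocity_mean_tp,mov_speed_tp,speed,transport,0.83,0.88,20.61,-9.99,TRUE,FALSE
velocity_max_tp,mov_speed_tp,speed,transport,0.83,0.87,18.57,-9.14,TRUE,FALSE
velocity_mean_rt,mov_speed_rt,speed,return,0.75,0.87,19.01,-7.60,TRUE,FALSE
velocity_max_rt,mov_speed_rt,speed,return,0.76,0.86,19.41,-6.27,TRUE,TRUE
position_error_peg_approach,endpoint_error_peg,endpoint_error,peg_approach,0.86,0.64,29.54,-4.66,TRUE,FALSE
jerk_peg_approach,endpoint_error_peg,endpoint_error,peg_approach,0.74,0.72,27.65,-2.94,TRUE,TRUE
log_jerk_peg_approach,endpoint_error_peg,endpoint_error,peg_approach,0.69,0.75,30.20,-8.36,TRUE,FALSE
sparc_peg_approach,endpoint_error_peg,endpoint_error,peg_approach,0.78,0.64,46.55,-10.29,TRUE,FALSE
position_error_hole_approach,endpoint_error_hole,endpoint_error,hole_approach,0.94,0.76,31.29,-5.36,TRUE,FALSE
jerk_hole_approach,endpoint_error_hole,endpoint_error,hole_approach,0.57,0.68,30.63,-4.84,TRUE,FALSE
log_jerk_hole_approach,endpoint_error_hole,endpoint_error,hole_approach,0.66,0.83,23.25,-6.53,TRUE,FALSE
sparc_hole_approach,endpoint_error_hole,endpoint_error,hole_approach,0.86,0.81,24.81,-5.72,TRUE,TRUE
haptic_collisions_mean_tp,haptic_collisions_tp,haptic,transport,0.61,0.85,24.55,-3.99,TRUE,FALSE
haptic_collisions_max_tp,haptic_collisions_tp,haptic,transport,0.63,0.84,20.54,-1.08,TRUE,FALSE
haptic_collisions_mean_rt,haptic_collisions_rt,haptic,return,0.61,0.72,25.32,-0.07,TRUE,FALSE
haptic_collisions_max_rt,haptic_collisions_rt,haptic,return,0.46,0.79,27.02,4.37,FALSE,FALSE
number_of_mov_onsets,number_of_movements,counts,whole_trial,0.22,0.22,61.34,-0.82,TRUE,FALSE
number_of_mov_ends,number_of_movements,counts,whole_trial,0.09,0.29,57.01,0.00,TRUE,FALSE
number_of_dropped_pegs,object_drops,drops,whole_trial,0.65,0.50,41.11,-3.20,TRUE,FALSE
gf_mean_tp,gf_scaling_tp,gf_scaling,transport,0.40,0.84,14.46,0.39,TRUE,FALSE
gf_max_tp,gf_scaling_tp,gf_scaling,transport,0.40,0.86,15.19,0.07,TRUE,FALSE
gf_rate_mean_tp,gf_scaling_tp,gf_scaling,transport,0.25,0.87,12.14,2.07,TRUE,FALSE
gf_rate_max_tp,gf_scaling_tp,gf_scaling,transport,0.25,0.79,20.53,3.93,TRUE,FALSE
gf_mean_rt,gf_scaling_rt,gf_scaling,return,0.49,0.76,27.62,0.17,TRUE,FALSE
gf_max_rt,gf_scaling_rt,gf_scaling,return,0.45,0.66,37.61,2.80,TRUE,FALSE
gf_rate_mean_rt,gf_scaling_rt,gf_scaling,return,0.07,0.82,27.79,5.87,TRUE,FALSE
gf_rate_max_rt,gf_scaling_rt,gf_scaling,return,0.29,0.48,34.05,7.19,TRUE,FALSE
gf_mean_peg_approach,gf_scaling_peg,gf_scaling,peg_approach,0.45,0.83,18.09,1.10,TRUE,FALSE
gf_max_peg_approach,gf_scaling_peg,gf_scaling,peg_approach,0.39,0.84,19.40,-0.72,TRUE,FALSE
gf_rate_mean_peg_approach,gf_scaling_peg,gf_scaling,peg_approach,0.18,0.88,14.76,3.54,TRUE,FALSE
gf_rate_max_peg_approach,gf_scaling_peg,gf_scaling,peg_approach,0.32,0.84,19.52,0.74,TRUE,FALSE
gf_mean_hole_approach,gf_scaling_hole,gf_scaling,hole_approach,0.36,0.81,15.34,0.76,TRUE,FALSE
gf_max_hole_approach,gf_scaling_hole,gf_scaling,hole_approach,0.37,0.82,16.43,0.50,TRUE,FALSE
gf_rate_mean_hole_approach,gf_scaling_hole,gf_scaling,hole_approach,0.15,0.82,14.18,2.73,TRUE,FALSE
gf_rate_max_hole_approach,gf_scaling_hole,gf_scaling,hole_approach,0.28,0.77,21.41,1.82,TRUE,FALSE
gf_rate_num_peaks_tp,gf_coordination_tp,gf_coordination,transport,0.74,0.81,20.59,-6.11,TRUE,TRUE
gf_rate_sparc_tp,gf_coordination_tp,gf_coordination,transport,0.74,0.82,22.48,-5.71,TRUE,TRUE
gf_rate_num_peaks_rt,gf_coordination_rt,gf_coordination,return,0.60,0.83,20.17,-4.16,TRUE,FALSE
gf_rate_sparc_rt,gf_coordination_rt,gf_coordination,return,0.64,0.78,23.81,-6.35,TRUE,FALSE
gf_rate_num_peaks_peg_approach,gf_coordination_peg,gf_coordination,peg_approach,0.90,0.78,25.60,-12.25,TRUE,FALSE
gf_rate_sparc_peg_approach,gf_coordination_peg,gf_coordination,peg_approach,0.90,0.83,22.99,-8.19,TRUE,FALSE
gf_rate_num_peaks_hole_approach,gf_coordination_hole,gf_coordination,hole_approach,0.91,0.81,24.29,-6.14,TRUE,TRUE
gf_rate_sparc_hole_approach,gf_coordination_hole,gf_coordination,hole_approach,0.84,0.82,26.38,-5.94,TRUE,TRUE
gf_rate_num_peaks_buildup,gf_coordination_buildup,gf_coordination,buildup,0.15,0.44,57.70,0.77,FALSE,FALSE
gf_rate_sparc_buildup,gf_coordination_buildup,gf_coordination,buildup,0.56,0.79,28.62,-3.22,FALSE,FALSE
gf_buildup_duration,gf_coordination_buildup,gf_coordination,buildup,0.70,0.82,21.36,-6.97,TRUE,FALSE
gf_rate_num_peaks_release,gf_coordination_release,gf_coordination,release,0.44,0.48,56.80,1.78,FALSE,FALSE
gf_rate_sparc_release,gf_coordination_release,gf_coordination,release,0.91,0.86,18.63,-6.78,TRUE,FALSE
gf_release_duration,gf_coordination_release,gf_coordination,release,0.67,0.81,21.63,-2.78,TRUE,FALSE
task_completion_time,overall_disability,overall,whole_trial,0.91,0.78,26.16,-11.34,TRUE,FALSE
simulated_gaussian_noise,control,control,whole_trial,0.37,-0.07,117.04,0.25,FALSE,FALSE
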