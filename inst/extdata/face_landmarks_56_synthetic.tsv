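name	x_mm	y_mm	z_mm	space_tag
right_eye_lateral	11	15.5	3	model
right_eye_medial	5	16.5	3	model
left_eye_medial	-5	16.5	3	model
left_eye_lateral	-11	15.5	3	model
right_eye_superior	8	16	5.5	model
right_eye_inferior	8	16	0.5	model
left_eye_superior	-8	16	5.5	model
left_eye_inferior	-8	16	0.5	model
right_pupil	8	16.5	3	model
left_pupil	-8	16.5	3	model
nasion	0	18.5	7	model
nose_bridge	0	19.5	3	model
nose_tip	0	23	-5	model
nose_base_mid	0	20	-8	model
right_ala	3.5	20.5	-7	model
left_ala	-3.5	20.5	-7	model
right_nostril_mid	1.8	21	-7.5	model
left_nostril_mid	-1.8	21	-7.5	model
columella	0	21.5	-7	model
mouth_seam_mid	0	17.5	-13	model
mouth_seam_right	4	17	-13	model
mouth_seam_left	-4	17	-13	model
right_mouth_corner	8	16	-13	model
left_mouth_corner	-8	16	-13	model
upper_lip_peak_mid	0	17.5	-11.5	model
lower_lip_peak_mid	0	17.5	-14.5	model
upper_lip_right	4	17	-11.5	model
upper_lip_left	-4	17	-11.5	model
lower_lip_right	4	17	-14.5	model
lower_lip_left	-4	17	-14.5	model
philtrum_mid	0	19	-10	model
pogonion	0	16	-19	model
chin_bottom	0	13	-22	model
chin_right	4	14.5	-20	model
chin_left	-4	14.5	-20	model
right_gonion	15	2	-16	model
left_gonion	-15	2	-16	model
right_jaw_mid	11	9	-18.5	model
left_jaw_mid	-11	9	-18.5	model
right_maxillary_process	13	10	-8	model
left_maxillary_process	-13	10	-8	model
right_ear	21	-3	-5	model
left_ear	-21	-3	-5	model
right_tragus	19.5	-1	-6	model
left_tragus	-19.5	-1	-6	model
glabella	0	19	8	model
forehead_mid	0	16.5	14	model
right_brow	8	17.5	8	model
left_brow	-8	17.5	8	model
right_temple	14	10	9	model
left_temple	-14	10	9	model
right_zygomatic_arch	18	8	0	model
left_zygomatic_arch	-18	8	0	model
right_zygoma_anterior	15	12	-2	model
left_zygoma_anterior	-15	12	-2	model
prosthion	0	18.5	-10.5	model
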