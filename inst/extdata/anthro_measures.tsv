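measure	landmark_a	landmark_b
left_eye_length	left_eye_medial	left_eye_lateral
right_eye_length	right_eye_medial	right_eye_lateral
left_eye_height	left_eye_superior	left_eye_inferior
right_eye_height	right_eye_superior	right_eye_inferior
mouth_width	right_mouth_corner	left_mouth_corner
craniofacial_width_ears	right_ear	left_ear
craniofacial_width_zygomatic	right_zygomatic_arch	left_zygomatic_arch
nose_width	right_ala	left_ala
filtrum_length	nose_base_mid	upper_lip_peak_mid
nose_to_chin	nose_base_mid	chin_bottom
lip_to_chin	lower_lip_peak_mid	chin_bottom
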