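vessel_id,vessel_name,length_cm,diameter_mm,h_over_r,E_kPa,is_vein,terminal_weight
ascending_aorta,Ascending aorta,4.0,29.0,0.11,400,0,0
aortic_arch_a1,Aortic arch A1,2.0,26.0,0.11,400,0,0
left_carotid,Left carotid artery,17.7,7.4,0.13,700,0,0.075
aortic_arch_a2,Aortic arch A2,3.9,24.5,0.11,400,0,0
thoracic_aorta,Thoracic aorta,15.6,20.0,0.11,400,0,0.78
right_subclavian,Right subclavian artery,3.4,8.5,0.15,400,0,0.05
vertebral,Vertebral artery,14.8,3.7,0.20,800,0,0.02
axillary_brachial,Axillary and brachial artery,40.0,5.0,0.15,900,0,0
radial,Radial artery,23.5,2.8,0.20,900,0,0
proximal_ulnar,Proximal ulnar artery,6.7,3.0,0.20,900,0,0
distal_ulnar,Distal ulnar artery,17.1,2.8,0.20,900,0,0
interosseus,Interosseus artery,7.9,1.8,0.20,900,0,0
left_subclavian,Left subclavian artery,3.4,8.5,0.15,400,0,0.05
innominate,Innominate artery,3.4,12.4,0.11,400,0,0
right_carotid,Right carotid artery,17.7,7.4,0.13,700,0,0.075
distal_cephalic,Distal cephalic vein,23.5,2.5,0.10,200,1,0
median_cubital,Median cubital vein,4.0,3.5,0.10,200,1,0
proximal_cephalic,Proximal cephalic vein,24.0,3.0,0.10,200,1,0
basilic,Basilic vein,24.0,3.5,0.10,200,1,0
axillary_subclavian_vein,Axillary and subclavian vein,16.0,8.0,0.10,200,1,0
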