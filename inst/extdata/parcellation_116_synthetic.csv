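"roi_name","network","hemisphere"
"LH_Vis_1","visual","L"
"LH_Vis_2","visual","L"
"LH_Vis_3","visual","L"
"LH_Vis_4","visual","L"
"LH_Vis_5","visual","L"
"LH_Vis_6","visual","L"
"LH_Vis_7","visual","L"
"LH_Vis_8","visual","L"
"LH_SomMot_1","somatomotor","L"
"LH_SomMot_2","somatomotor","L"
"LH_SomMot_3","somatomotor","L"
"LH_SomMot_4","somatomotor","L"
"LH_SomMot_5","somatomotor","L"
"LH_SomMot_6","somatomotor","L"
"LH_SomMot_7","somatomotor","L"
"LH_DorsAttn_1","dorsal attention","L"
"LH_DorsAttn_2","dorsal attention","L"
"LH_DorsAttn_3","dorsal attention","L"
"LH_DorsAttn_4","dorsal attention","L"
"LH_DorsAttn_5","dorsal attention","L"
"LH_DorsAttn_6","dorsal attention","L"
"LH_DorsAttn_7","dorsal attention","L"
"LH_SalVentAttn_1","salience/ventral attention","L"
"LH_SalVentAttn_2","salience/ventral attention","L"
"LH_SalVentAttn_3","salience/ventral attention","L"
"LH_SalVentAttn_4","salience/ventral attention","L"
"LH_SalVentAttn_5","salience/ventral attention","L"
"LH_SalVentAttn_6","salience/ventral attention","L"
"LH_SalVentAttn_7","salience/ventral attention","L"
"LH_Limbic_1","limbic","L"
"LH_Limbic_2","limbic","L"
"LH_Limbic_3","limbic","L"
"LH_Limbic_4","limbic","L"
"LH_Limbic_5","limbic","L"
"LH_Limbic_6","limbic","L"
"LH_Limbic_7","limbic","L"
"LH_Cont_1","control","L"
"LH_Cont_2","control","L"
"LH_Cont_3","control","L"
"LH_Cont_4","control","L"
"LH_Cont_5","control","L"
"LH_Cont_6","control","L"
"LH_Cont_7","control","L"
"LH_Default_1","DMN","L"
"LH_Default_2","DMN","L"
"LH_Default_3","DMN","L"
"LH_Default_4","DMN","L"
"LH_Default_5","DMN","L"
"LH_Default_6","DMN","L"
"LH_Default_7","DMN","L"
"RH_Vis_1","visual","R"
"RH_Vis_2","visual","R"
"RH_Vis_3","visual","R"
"RH_Vis_4","visual","R"
"RH_Vis_5","visual","R"
"RH_Vis_6","visual","R"
"RH_Vis_7","visual","R"
"RH_Vis_8","visual","R"
"RH_SomMot_1","somatomotor","R"
"RH_SomMot_2","somatomotor","R"
"RH_SomMot_3","somatomotor","R"
"RH_SomMot_4","somatomotor","R"
"RH_SomMot_5","somatomotor","R"
"RH_SomMot_6","somatomotor","R"
"RH_SomMot_7","somatomotor","R"
"RH_DorsAttn_1","dorsal attention","R"
"RH_DorsAttn_2","dorsal attention","R"
"RH_DorsAttn_3","dorsal attention","R"
"RH_DorsAttn_4","dorsal attention","R"
"RH_DorsAttn_5","dorsal attention","R"
"RH_DorsAttn_6","dorsal attention","R"
"RH_DorsAttn_7","dorsal attention","R"
"RH_SalVentAttn_1","salience/ventral attention","R"
"RH_SalVentAttn_2","salience/ventral attention","R"
"RH_SalVentAttn_3","salience/ventral attention","R"
"RH_SalVentAttn_4","salience/ventral attention","R"
"RH_SalVentAttn_5","salience/ventral attention","R"
"RH_SalVentAttn_6","salience/ventral attention","R"
"RH_SalVentAttn_7","salience/ventral attention","R"
"RH_Limbic_1","limbic","R"
"RH_Limbic_2","limbic","R"
"RH_Limbic_3","limbic","R"
"RH_Limbic_4","limbic","R"
"RH_Limbic_5","limbic","R"
"RH_Limbic_6","limbic","R"
"RH_Limbic_7","limbic","R"
"RH_Cont_1","control","R"
"RH_Cont_2","control","R"
"RH_Cont_3","control","R"
"RH_Cont_4","control","R"
"RH_Cont_5","control","R"
"RH_Cont_6","control","R"
"RH_Cont_7","control","R"
"RH_Default_1","DMN","R"
"RH_Default_2","DMN","R"
"RH_Default_3","DMN","R"
"RH_Default_4","DMN","R"
"RH_Default_5","DMN","R"
"RH_Default_6","DMN","R"
"RH_Default_7","DMN","R"
"LH_Subcort_1","subcortical","L"
"LH_Subcort_2","subcortical","L"
"LH_Subcort_3","subcortical","L"
"LH_Subcort_4","subcortical","L"
"LH_Subcort_5","subcortical","L"
"LH_Subcort_6","subcortical","L"
"LH_Subcort_7","subcortical","L"
"LH_Subcort_8","subcortical","L"
"RH_Subcort_1","subcortical","R"
"RH_Subcort_2","subcortical","R"
"RH_Subcort_3","subcortical","R"
"RH_Subcort_4","subcortical","R"
"RH_Subcort_5","subcortical","R"
"RH_Subcort_6","subcortical","R"
"RH_Subcort_7","subcortical","R"
"RH_Subcort_8","subcortical","R"
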