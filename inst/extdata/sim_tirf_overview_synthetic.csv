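organism,genotype,channel,image_id,n_maxima,lysate_volume
Arabidopsis,wild_type,protein,At_wt_prot_1,512,100
Arabidopsis,wild_type,protein,At_wt_prot_2,488,100
Arabidopsis,wild_type,protein,At_wt_prot_3,521,100
Arabidopsis,wild_type,protein,At_wt_prot_4,479,100
Arabidopsis,wild_type,oligo,At_wt_oligo_1,46,50
Arabidopsis,wild_type,oligo,At_wt_oligo_2,55,50
Arabidopsis,wild_type,oligo,At_wt_oligo_3,51,50
Arabidopsis,wild_type,oligo,At_wt_oligo_4,48,50
Arabidopsis,atm-2,protein,At_atm_prot_1,495,100
Arabidopsis,atm-2,protein,At_atm_prot_2,509,100
Arabidopsis,atm-2,protein,At_atm_prot_3,502,100
Arabidopsis,atm-2,protein,At_atm_prot_4,494,100
Arabidopsis,atm-2,oligo,At_atm_oligo_1,92,50
Arabidopsis,atm-2,oligo,At_atm_oligo_2,98,50
Arabidopsis,atm-2,oligo,At_atm_oligo_3,90,50
Arabidopsis,atm-2,oligo,At_atm_oligo_4,94,50
S_cerevisiae,wild_type,protein,Sc_wt_prot_1,310,10
S_cerevisiae,wild_type,protein,Sc_wt_prot_2,295,10
S_cerevisiae,wild_type,protein,Sc_wt_prot_3,288,10
S_cerevisiae,wild_type,protein,Sc_wt_prot_4,312,10
S_cerevisiae,wild_type,protein,Sc_wt_prot_5,295,10
S_cerevisiae,wild_type,oligo,Sc_wt_oligo_1,63,10
S_cerevisiae,wild_type,oligo,Sc_wt_oligo_2,58,10
S_cerevisiae,wild_type,oligo,Sc_wt_oligo_3,61,10
S_cerevisiae,wild_type,oligo,Sc_wt_oligo_4,60,10
S_cerevisiae,wild_type,oligo,Sc_wt_oligo_5,58,10
S_cerevisiae,tel1d,protein,Sc_tel1_prot_1,302,10
S_cerevisiae,tel1d,protein,Sc_tel1_prot_2,297,10
S_cerevisiae,tel1d,protein,Sc_tel1_prot_3,305,10
S_cerevisiae,tel1d,protein,Sc_tel1_prot_4,301,10
S_cerevisiae,tel1d,protein,Sc_tel1_prot_5,295,10
S_cerevisiae,tel1d,oligo,Sc_tel1_oligo_1,127,10
S_cerevisiae,tel1d,oligo,Sc_tel1_oligo_2,129,10
S_cerevisiae,tel1d,oligo,Sc_tel1_oligo_3,124,10
S_cerevisiae,tel1d,oligo,Sc_tel1_oligo_4,128,10
S_cerevisiae,tel1d,oligo,Sc_tel1_oligo_5,125,10
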