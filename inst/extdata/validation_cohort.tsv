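# Validation cohort for the ALK coverage-asymmetry predictor: 50 samples.
# 19 individually reported validation rows (coverage prediction vs targeted
# NGS panel confirmation) plus 31 screening controls that were negative by
# both prediction and panel sequencing; the controls are encoded here only
# as their aggregate negative/negative outcome (CTRL_01..CTRL_31).
sample_id	predicted_positive	confirmed_positive
ALK_1_2	TRUE	TRUE
ALK_2	TRUE	TRUE
ALK_3	FALSE	FALSE
ALK_4	TRUE	TRUE
ALK_5	TRUE	TRUE
ALK_6_2	FALSE	FALSE
ALK_8	TRUE	TRUE
ALK_9	TRUE	TRUE
ALK_10	TRUE	TRUE
ALK_12	TRUE	TRUE
ALK_14	FALSE	FALSE
ALK_15	FALSE	FALSE
ALK_16	TRUE	TRUE
LuC_62	TRUE	TRUE
LuC_68	TRUE	FALSE
LuC_103	FALSE	FALSE
LuC_104	TRUE	TRUE
NS_20	FALSE	FALSE
OC_25	TRUE	FALSE
CTRL_01	FALSE	FALSE
CTRL_02	FALSE	FALSE
CTRL_03	FALSE	FALSE
CTRL_04	FALSE	FALSE
CTRL_05	FALSE	FALSE
CTRL_06	FALSE	FALSE
CTRL_07	FALSE	FALSE
CTRL_08	FALSE	FALSE
CTRL_09	FALSE	FALSE
CTRL_10	FALSE	FALSE
CTRL_11	FALSE	FALSE
CTRL_12	FALSE	FALSE
CTRL_13	FALSE	FALSE
CTRL_14	FALSE	FALSE
CTRL_15	FALSE	FALSE
CTRL_16	FALSE	FALSE
CTRL_17	FALSE	FALSE
CTRL_18	FALSE	FALSE
CTRL_19	FALSE	FALSE
CTRL_20	FALSE	FALSE
CTRL_21	FALSE	FALSE
CTRL_22	FALSE	FALSE
CTRL_23	FALSE	FALSE
CTRL_24	FALSE	FALSE
CTRL_25	FALSE	FALSE
CTRL_26	FALSE	FALSE
CTRL_27	FALSE	FALSE
CTRL_28	FALSE	FALSE
CTRL_29	FALSE	FALSE
CTRL_30	FALSE	FALSE
CTRL_31	FALSE	FALSE
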