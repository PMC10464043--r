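patient_id,group,fev1_l,pefr_ls,fvc_l,vc_l,sex,age_years,bmi,etiology
sgs_01,SGS,2.8453608419587386,4.169119473787891,,,,,,
sgs_02,SGS,1.3019551633223099,2.5781675894184812,,,,,,
sgs_03,SGS,5.879099437143191,11.420374764590942,,,,,,
sgs_04,SGS,1.8827344820197565,3.1165537882003935,,,,,,
sgs_05,SGS,2.8826909440777553,4.878779747435308,,,,,,
sgs_06,SGS,3.2408320359725,4.5127719737944965,,,,,,
sgs_07,SGS,6.270779352414861,7.607907882489326,,,,,,
sgs_08,SGS,1.1703515217723353,2.368175999920007,,,,,,
sgs_09,SGS,2.9172686274330086,3.3819355783849825,,,,,,
sgs_10,SGS,4.8043182456357885,7.380602869662665,,,,,,
sgs_11,SGS,3.4260143896841315,4.8447122133504115,,,,,,
sgs_12,SGS,2.251909121476999,2.8522222785069085,,,,,,
sgs_13,SGS,2.689106888828417,4.95353743889695,,,,,,
sgs_14,SGS,2.8766493421336183,4.450835780169203,,,,,,
sgs_15,SGS,3.552764209122381,5.369555125738085,,,,,,
sgs_16,SGS,2.9182125280221225,3.6999522409182783,,,,,,
sgs_17,SGS,2.0001945438443816,3.523125234065036,,,,,,
sgs_18,SGS,2.4729208497174517,3.526504461189906,,,,,,
sgs_19,SGS,4.898458395561727,7.042565619400729,,,,,,
sgs_20,SGS,3.602365755485678,5.181903968862882,,,,,,
sgs_21,SGS,3.833770402535626,4.932732080424658,,,,,,
sgs_22,SGS,2.07470548434121,3.5124570224157905,,,,,,
sgs_23,SGS,1.7497775424983764,3.3504401277195153,,,,,,
sgs_24,SGS,2.5425626735565596,4.193650127098222,,,,,,
sgs_25,SGS,1.7017984523078036,3.242356815577939,,,,,,
sgs_26,SGS,2.5595975462238045,4.062068975599246,,,,,,
sgs_27,SGS,2.619505176938824,2.8894194840147884,,,,,,
sgs_28,SGS,2.1373323333368517,2.6733947031008056,,,,,,
sgs_29,SGS,3.4181626292799763,5.829076997788802,,,,,,
sgs_30,SGS,3.924679716054753,6.372932469670207,,,,,,
sgs_31,SGS,1.962784918827112,2.5873645317105534,,,,,,
sgs_32,SGS,1.2096125343268,2.4556434720381968,,,,,,
sgs_33,SGS,1.793400648015397,3.5325368963519725,,,,,,
sgs_34,SGS,2.6743755189140916,4.97903840547597,,,,,,
sgs_35,SGS,3.1607220290664833,3.632307797340577,,,,,,
sgs_36,SGS,3.903435729257323,4.885070168305965,,,,,,
sgs_37,SGS,1.8500523312113166,3.1244261805511426,,,,,,
sgs_38,SGS,1.1074357846363507,1.6821802148564653,,,,,,
sgs_39,SGS,2.1526042587357064,3.55227264902977,,,,,,
sgs_40,SGS,1.943950322146588,2.8749087338607637,,,,,,
sgs_41,SGS,1.6855265267455615,2.435717359663103,,,,,,
sgs_42,SGS,1.987477373813244,3.7139894580240314,,,,,,
sgs_43,SGS,1.588186050574351,2.5468358759131307,,,,,,
sgs_44,SGS,1.507244357336474,3.014583378455374,,,,,,
sgs_45,SGS,0.2693,1,,,,,,
sgs_46,SGS,0.3514,1,,,,,,
sgs_47,SGS,0.36060000000000003,1,,,,,,
sgs_48,SGS,0.37200000000000005,1,,,,,,
sgs_49,SGS,0.4064,1,,,,,,
sgs_50,SGS,0.4568,1,,,,,,
asthma_01,asthma,2.23013619830005,4.0685898359284876,,,,,,
asthma_02,asthma,1.916862629412344,3.323265462076165,,,,,,
asthma_03,asthma,3.530596453158909,6.812042209607662,,,,,,
asthma_04,asthma,8.17979418017746,14.577679257303366,,,,,,
asthma_05,asthma,1.9730639876823628,3.7418741891182856,,,,,,
asthma_06,asthma,2.9267713508192488,6.67410627974508,,,,,,
asthma_07,asthma,0.8617911714011126,3.1638659640386644,,,,,,
asthma_08,asthma,3.640463812762683,10.86768473674853,,,,,,
asthma_09,asthma,1.0277439145423177,2.6055160167422367,,,,,,
asthma_10,asthma,4.9099383021177445,10.440604067250081,,,,,,
asthma_11,asthma,4.225146143737688,14.001885648159268,,,,,,
asthma_12,asthma,2.353978419934844,4.949648011188781,,,,,,
asthma_13,asthma,2.546458456194101,6.482857225222326,,,,,,
asthma_14,asthma,2.1046706569149767,5.215110753375205,,,,,,
asthma_15,asthma,3.4950044279416477,7.526988859953866,,,,,,
asthma_16,asthma,1.8417853267179893,4.627588838181853,,,,,,
asthma_17,asthma,1.7982261785159686,6.456301606192277,,,,,,
asthma_18,asthma,1.6638843968294714,6.228124286800337,,,,,,
asthma_19,asthma,2.7865691912188293,6.996704003153924,,,,,,
asthma_20,asthma,2.221986149622251,5.021528316037723,,,,,,
asthma_21,asthma,5.026915533968697,12.510348937689292,,,,,,
asthma_22,asthma,4.679914163001734,12.407222503174458,,,,,,
asthma_23,asthma,4.323023720957781,11.879895516087219,,,,,,
asthma_24,asthma,2.7726369177864587,6.553501167820985,,,,,,
asthma_25,asthma,1.7673618237004844,6.810626522607223,,,,,,
asthma_26,asthma,3.5454564067926966,9.49246728708706,,,,,,
asthma_27,asthma,2.307518971415216,5.048619727938194,,,,,,
asthma_28,asthma,2.180464565850019,6.070888944041736,,,,,,
asthma_29,asthma,1.275916671883327,3.0275277016093503,,,,,,
asthma_30,asthma,4.1445507999406574,9.522201717562156,,,,,,
asthma_31,asthma,3.1332358863282512,8.039159087231692,,,,,,
asthma_32,asthma,1.73723265590723,4.095925601116849,,,,,,
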