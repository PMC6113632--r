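 0.00000000000 -0.42874833714  0.12278356587 -0.91180104565 -0.92784814200  0.98314277452  0.25883692430  0.77574663797 -0.00031922337  0.83589015971 -0.34833338981 -0.67291826372 -0.56007071994  0.02936765972  0.93139220690 -0.73827080744  0.55645678121 -0.41881019060 -0.49685396408  0.74672468124 -0.79331251522 -0.09487402295 -0.44202450898 -0.32756211418  0.33058558430  0.14654033815 -0.43870112486 -0.66343479078  0.13194035281  0.21025585890 -0.64653394124
 0.00000000000 -0.89376143610 -0.75432609463  0.33768602096 -0.36695715162 -0.06234510701 -0.94450223437 -0.14751038681  0.97570795584 -0.49141119068 -0.74168932173  0.73020405078  0.63043355775  0.02003642948  0.12626781327  0.18204926230 -0.56741298916 -0.05542080059 -0.15539983854  0.59703709253 -0.31927250916  0.77997441956  0.85744029636  0.39677851143 -0.30965934797  0.44252387767 -0.64952211037 -0.71345890760  0.45640540797  0.93469522622 -0.35901573522
 0.00000000000  0.13177768680  0.64491576110  0.23363861923 -0.06663538300  0.17188185633 -0.20228439358  0.61356160201 -0.21907506250  0.24454587008  0.57320223270  0.11824996650  0.53747029492  0.99936784122 -0.34141616286  0.64947230963  0.60695827730  0.90638102314 -0.85380737205 -0.29317053156 -0.51838240527  0.61857806670 -0.26345867159  0.85747878937  0.89152916928 -0.88470251892 -0.62101719074 -0.22545657130  0.87993513788  0.28659607093  0.67312819335
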